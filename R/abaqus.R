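#' Write a mesh and material field as an Abaqus input deck
#'
#' Emits the subset of Abaqus syntax needed to re-run a model elsewhere:
#' `*NODE`, `*ELEMENT, TYPE=C3D8`, per-modulus element sets with
#' `*SOLID SECTION` / `*MATERIAL` / `*ELASTIC` blocks, the `bottom_face` /
#' `top_face` node sets, and a `*BOUNDARY` block clamping the bottom face
#' and prescribing the axial plate displacement. Ids are 1-based in the
#' file. Element moduli are grouped into at most `nBins` material sections
#' (255 by default, mirroring the 8-bit grayscale resolution); when there
#' are no more distinct moduli than bins, each distinct value keeps its
#' exact modulus and the file round-trips losslessly.
#'
#' @param mesh a [HexMesh-class].
#' @param materials a [MaterialField-class].
#' @param loadcase a [LoadCase-class].
#' @param path output file path (`.inp`).
#' @param nBins maximum number of material sections.
#' @return `path`, invisibly.
#' @export
writeAbaqusInp <- function(mesh, materials, loadcase = loadCase(), path,
                           nBins = 255L) {
  stopifnot(is(mesh, "HexMesh"), is(materials, "MaterialField"),
            length(materials@E) == nrow(mesh@elements))
  E <- materials@E
  uniq <- sort(unique(E))
  if (length(uniq) <= nBins) {
    grp <- match(E, uniq)
    grpE <- uniq
  } else {
    br <- seq(min(E), max(E), length.out = nBins + 1L)
    grp <- pmin(findInterval(E, br, rightmost.closed = TRUE), nBins)
    grpE <- vapply(seq_len(nBins), function(g) mean(E[grp == g]), 0)
    keep <- !is.na(grpE)
    grp <- match(grp, which(keep))
    grpE <- grpE[keep]
  }
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("*HEADING", "vertefem voxel hexahedral model")
  w("*NODE")
  w(sprintf("%d, %.10g, %.10g, %.10g", seq_len(nrow(mesh@nodes)),
            mesh@nodes[, 1], mesh@nodes[, 2], mesh@nodes[, 3]))
  w("*ELEMENT, TYPE=C3D8")
  el <- mesh@elements
  w(sprintf("%d, %d, %d, %d, %d, %d, %d, %d, %d", seq_len(nrow(el)),
            el[, 1], el[, 2], el[, 3], el[, 4],
            el[, 5], el[, 6], el[, 7], el[, 8]))
  writeIdList <- function(ids) {
    for (i in seq(1L, length(ids), by = 16L))
      w(paste(ids[i:min(i + 15L, length(ids))], collapse = ", "))
  }
  for (nm in c("bone", "cement")) {
    ids <- mesh@elementSets[[nm]]
    if (length(ids)) {
      w(sprintf("*ELSET, ELSET=%s", toupper(nm)))
      writeIdList(ids)
    }
  }
  for (g in seq_along(grpE)) {
    w(sprintf("*ELSET, ELSET=MAT%d", g))
    writeIdList(which(grp == g))
  }
  for (g in seq_along(grpE)) {
    w(sprintf("*SOLID SECTION, ELSET=MAT%d, MATERIAL=MAT%d", g, g))
    w(sprintf("*MATERIAL, NAME=MAT%d", g))
    w("*ELASTIC")
    w(sprintf("%.10g, %.10g", grpE[g], materials@nu))
  }
  for (nm in c("bottom_face", "top_face")) {
    w(sprintf("*NSET, NSET=%s", toupper(nm)))
    writeIdList(mesh@nodeSets[[nm]])
  }
  w("*BOUNDARY")
  w("BOTTOM_FACE, 1, 3, 0.0")
  w(sprintf("TOP_FACE, 3, 3, %.10g", loadcase@displacement))
  invisible(path)
}

#' Read back the Abaqus input subset written by [writeAbaqusInp()]
#'
#' @param path `.inp` file path.
#' @return A list: `mesh` (a [HexMesh-class]; `elementSource` is unknown and
#'   set to zero), `E` (per-element modulus, GPa), `nu`, and `displacement`
#'   (the prescribed axial value in the `*BOUNDARY` block, if present).
#' @export
readAbaqusInp <- function(path) {
  ln <- readLines(path)
  isKey <- startsWith(ln, "*")
  key <- toupper(ln)
  blocks <- split(seq_along(ln), cumsum(isKey))
  nodes <- NULL; elements <- NULL
  elsets <- list(); matE <- list(); sectionMat <- list()
  nu <- NA_real_; displacement <- NA_real_
  pendingElastic <- NULL
  for (b in blocks) {
    head <- key[b[1]]
    body <- ln[b[-1]]
    body <- body[nzchar(trimws(body))]
    parseNums <- function(x) lapply(strsplit(x, ","), function(v) as.numeric(trimws(v)))
    if (startsWith(head, "*NODE")) {
      m <- do.call(rbind, parseNums(body))
      nodes <- m[order(m[, 1]), 2:4, drop = FALSE]
    } else if (startsWith(head, "*ELEMENT")) {
      m <- do.call(rbind, parseNums(body))
      elements <- m[order(m[, 1]), 2:9, drop = FALSE]
    } else if (startsWith(head, "*ELSET")) {
      nm <- sub(".*ELSET=([^,]+).*", "\\1", head)
      elsets[[nm]] <- as.integer(unlist(parseNums(body)))
    } else if (startsWith(head, "*SOLID SECTION")) {
      nm <- sub(".*ELSET=([^,]+).*", "\\1", head)
      mt <- sub(".*MATERIAL=([^,]+).*", "\\1", head)
      sectionMat[[mt]] <- nm
    } else if (startsWith(head, "*MATERIAL")) {
      pendingElastic <- sub(".*NAME=([^,]+).*", "\\1", head)
    } else if (startsWith(head, "*ELASTIC")) {
      v <- parseNums(body)[[1]]
      matE[[pendingElastic]] <- v[1]
      nu <- v[2]
    } else if (startsWith(head, "*BOUNDARY")) {
      for (row in body) {
        v <- strsplit(row, ",")[[1]]
        if (length(v) >= 4) displacement <- as.numeric(trimws(v[4]))
      }
    } else if (startsWith(head, "*NSET")) {
      nm <- tolower(sub(".*NSET=([^,]+).*", "\\1", head))
      elsets[[paste0("nset_", nm)]] <- as.integer(unlist(parseNums(body)))
    }
  }
  if (is.null(nodes) || is.null(elements))
    stop("input deck lacks *NODE or *ELEMENT blocks")
  nEl <- nrow(elements)
  E <- rep(NA_real_, nEl)
  for (mt in names(matE)) {
    setName <- sectionMat[[mt]]
    if (!is.null(setName)) E[elsets[[setName]]] <- matE[[mt]]
  }
  edge <- abs(nodes[elements[1, 2], ] - nodes[elements[1, 1], ])
  spacing <- c(max(edge), max(edge), max(edge))
  # recover per-axis edges from the first element's corner coordinates
  p <- nodes[elements[1, ], , drop = FALSE]
  spacing <- apply(p, 2, function(v) diff(range(v)))
  mesh <- new("HexMesh", nodes = nodes, elements = matrix(as.integer(elements), nEl, 8),
              elementSource = integer(nEl), spacing = spacing,
              nodeSets = list(bottom_face = elsets[["nset_bottom_face"]],
                              top_face = elsets[["nset_top_face"]]),
              elementSets = list(bone = if (is.null(elsets$BONE)) integer(0) else elsets$BONE,
                                 cement = if (is.null(elsets$CEMENT)) integer(0) else elsets$CEMENT))
  list(mesh = mesh, E = E, nu = nu, displacement = displacement)
}
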