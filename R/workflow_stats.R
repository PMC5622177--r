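#' Lin's concordance correlation coefficient
#'
#' Agreement between two paired series, combining correlation with
#' deviation from the identity line:
#' `ccc = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, with
#' population (1/n) moments as in Lin's original definition — a deliberate
#' choice documented because study group sizes here are small (6-8).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return CCC in \[-1, 1\]; 1 only for perfect identity agreement.
#' @examples
#' linCCC(1:3, 2:4)     # 4/7
#' linCCC(1:3, 3:1)     # -1
#' @export
linCCC <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("'x' and 'y' must have equal length >= 2")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0) {
    if (mx == my) return(1)
    stop("both series are constant and unequal; CCC undefined")
  }
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are `y - x`; the bias is their mean and the limits of
#' agreement are `bias +/- 1.96 * sd` with the sample (1/(n-1)) standard
#' deviation.
#'
#' @param x,y numeric vectors of equal length >= 2 (e.g. in vitro and in
#'   silico stiffness).
#' @return A list: `bias`, `loaLow`, `loaHigh`, and a data.frame `pairs`
#'   with per-pair means and differences.
#' @export
blandAltman <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("'x' and 'y' must have equal length >= 2")
  diffs <- y - x
  bias <- mean(diffs)
  s <- sd(diffs)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       pairs = data.frame(mean = (x + y) / 2, diff = diffs))
}

#' Agreement report between in vitro and in silico stiffness
#'
#' Bundles Lin's CCC, Pearson correlation and the Bland-Altman statistics
#' for one species.
#'
#' @param invitro,insilico paired stiffness values, kN/mm.
#' @return An [AgreementReport-class].
#' @export
agreementReport <- function(invitro, insilico) {
  ba <- blandAltman(invitro, insilico)
  pr <- suppressWarnings(cor(invitro, insilico))
  new("AgreementReport", ccc = linCCC(invitro, insilico),
      pearson = if (is.na(pr)) NA_real_ else pr,
      bias = ba$bias, loa = c(ba$loaLow, ba$loaHigh),
      n = as.integer(length(invitro)), pairs = ba$pairs)
}

#' Compare a variable between species groups
#'
#' Shapiro-Wilk normality per group (constant groups are flagged, not
#' tested), a Kruskal-Wallis omnibus test, and pairwise unpaired rank-sum
#' tests with raw (uncorrected) p-values. The rank tests are delegated to
#' the standard library implementations; this package only orchestrates
#' them.
#'
#' @param values named list of numeric vectors, one per group, each of
#'   length >= 3; at least 2 groups.
#' @return A [GroupComparisonReport-class].
#' @export
compareGroups <- function(values) {
  if (length(values) < 2L) stop("need at least 2 groups")
  if (any(vapply(values, length, 0L) < 3L))
    stop("every group needs at least 3 values")
  sw <- do.call(rbind, lapply(names(values), function(nm) {
    v <- values[[nm]]
    if (length(unique(v)) == 1L)
      return(data.frame(group = nm, W = NA_real_, p = NA_real_,
                        applicable = FALSE))
    t <- shapiro.test(v)
    data.frame(group = nm, W = unname(t$statistic), p = t$p.value,
               applicable = TRUE)
  }))
  kw <- kruskal.test(values)
  prs <- utils::combn(names(values), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    t <- suppressWarnings(wilcox.test(values[[a]], values[[b]], exact = FALSE))
    data.frame(groupA = a, groupB = b, W = unname(t$statistic),
               p = t$p.value)
  }))
  new("GroupComparisonReport", shapiro = sw,
      kruskal = list(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p = kw$p.value),
      pairwise = pw)
}
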