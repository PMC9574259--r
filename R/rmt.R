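# Random-matrix-theory threshold selection for co-occurrence networks.
#
# Rationale: below the "right" cutoff a thresholded correlation matrix keeps
# enough noise that its unfolded eigenvalue nearest-neighbour spacings follow
# the Gaussian orthogonal ensemble (Wigner surmise); once only modular signal
# remains, the spectrum decomposes into near-independent blocks and the
# spacings turn Poisson. The scan picks the first cutoff where the Poisson
# fit wins stably.

# Unfold a sorted eigenvalue spectrum with a degree-`degree` polynomial fit
# to the cumulative spectral function, then return normalized spacings.
unfold_spacings <- function(ev, degree = 5) {
  ev <- sort(ev)
  n <- length(ev)
  if (n < degree + 2 || stats::sd(ev) < 1e-12) return(NULL)
  fit <- stats::lm(seq_len(n) ~ stats::poly(ev, degree))
  smoothed <- sort(stats::fitted(fit))   # enforce monotone unfolded positions
  s <- diff(smoothed)
  s <- s[is.finite(s) & s >= 0]
  if (length(s) < 10 || mean(s) <= 0) return(NULL)
  s / mean(s)
}

# Chi-square goodness of fit of spacings to a theoretical spacing CDF.
spacing_chi2 <- function(s, cdf, n_bins = 20) {
  breaks <- c(seq(0, 3, length.out = n_bins), Inf)
  obs <- as.vector(table(cut(s, breaks, include.lowest = TRUE)))
  p <- diff(cdf(breaks))
  p[p < 1e-12] <- 1e-12
  expd <- length(s) * p / sum(p)
  sum((obs - expd)^2 / expd)
}

poisson_cdf <- function(x) ifelse(is.finite(x), 1 - exp(-x), 1)
goe_cdf <- function(x) ifelse(is.finite(x), 1 - exp(-pi * x^2 / 4), 1)

#' Random matrix theory threshold scan
#'
#' For each candidate cutoff, entries of the association matrix below the
#' cutoff (in absolute value) are zeroed, taxa left without any off-diagonal
#' entry are removed, and the nearest-neighbour spacing distribution (NNSD)
#' of the unfolded eigenvalues is scored against the Poisson law
#' \eqn{e^{-s}} and the GOE Wigner surmise by chi-square over binned
#' spacings. The chosen threshold is the first grid point at which the
#' Poisson fit beats the GOE fit for `consecutive` consecutive points — the
#' transition from random-matrix noise to modular structure.
#'
#' @param assoc an `assoc_matrix`.
#' @param grid strictly increasing cutoff candidates in (0, 1).
#' @param consecutive how many consecutive Poisson wins define the
#'   transition (guards against single-point noise flips).
#' @param n_bins spacing histogram bins for the chi-square.
#' @param unfold_degree degree of the polynomial spectral unfolding.
#' @param min_taxa smallest retained matrix considered spectrally meaningful.
#' @return list of class `rmt_scan` with `scan` (data.frame: cutoff,
#'   n_taxa, poisson_chi2, goe_chi2) and `chosen` (selected cutoff).
#' @export
rmt_threshold_scan <- function(assoc, grid = seq(0.30, 0.95, by = 0.01),
                               consecutive = 3, n_bins = 20,
                               unfold_degree = 5, min_taxa = 20) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid >= 1))
    stop("grid must be strictly increasing within (0, 1)", call. = FALSE)
  if (nrow(assoc$r) < min_taxa)
    stop(sprintf("need >= %d taxa for a meaningful spectrum", min_taxa),
         call. = FALSE)
  scan <- data.frame(cutoff = grid, n_taxa = NA_integer_,
                     poisson_chi2 = NA_real_, goe_chi2 = NA_real_)
  for (k in seq_along(grid)) {
    m <- assoc$r
    m[abs(m) < grid[k]] <- 0
    diag(m) <- 1
    connected <- rowSums(m != 0) > 1
    m <- m[connected, connected, drop = FALSE]
    scan$n_taxa[k] <- nrow(m)
    if (nrow(m) < min_taxa) next
    s <- unfold_spacings(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                         unfold_degree)
    if (is.null(s)) next
    scan$poisson_chi2[k] <- spacing_chi2(s, poisson_cdf, n_bins)
    scan$goe_chi2[k] <- spacing_chi2(s, goe_cdf, n_bins)
  }
  wins <- !is.na(scan$poisson_chi2) & !is.na(scan$goe_chi2) &
    scan$poisson_chi2 < scan$goe_chi2
  chosen <- NA_real_
  run <- rle(wins)
  ends <- cumsum(run$lengths)
  ok <- which(run$values & run$lengths >= consecutive)
  if (length(ok) > 0)
    chosen <- grid[ends[ok[1]] - run$lengths[ok[1]] + 1]
  if (is.na(chosen))
    mn_stop("scan_failed", "no cutoff reaches a stable Poisson NNSD fit",
            data = scan)
  structure(list(scan = scan, chosen = chosen), class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("rmt_scan: %d cutoffs scanned, chosen threshold %.2f\n",
              nrow(x$scan), x$chosen))
  invisible(x)
}
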