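# Biweight midcorrelation.
#
# For a vector x the biweight midcovariance transform is
#   u_i = (x_i - med(x)) / (9 * mad(x)),       mad unscaled (constant 1)
#   w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]
#   x~_i = (x_i - med(x)) * w_i
# and bicor(x, y) = sum(x~ y~) / (||x~|| ||y~||). Rows with mad = 0 cannot
# be robustly standardized and fall back to Pearson centering (mean) for
# that row, with a warning.

# transform one vector; returns the weighted, centered values (not normalized)
bicor_transform <- function(x, pearson_fallback = FALSE) {
  if (pearson_fallback) return(x - mean(x))
  med <- stats::median(x)
  m <- stats::mad(x, constant = 1)
  u <- (x - med) / (9 * m)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

# bicor for a pair of complete vectors (used for trait correlation);
# a column is treated as Pearson when its mad is 0 or it is dichotomous,
# mirroring robust-correlation practice for binary codings.
bicor_pair <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stopf("bicor requires at least 4 paired observations")
  fb_x <- stats::mad(x, constant = 1) == 0 || length(unique(x)) <= 2
  fb_y <- stats::mad(y, constant = 1) == 0 || length(unique(y)) <= 2
  if ((fb_x && stats::sd(x) == 0) || (fb_y && stats::sd(y) == 0))
    return(NA_real_)
  xt <- bicor_transform(x, fb_x)
  yt <- bicor_transform(y, fb_y)
  r <- sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
  min(1, max(-1, r))
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation between all pairs of proteins (rows). Observations are
#' median-centered and downweighted by the Tukey biweight with the usual
#' 9-mad radius, so single outlying samples cannot dominate a correlation.
#' Proteins whose median absolute deviation is zero are Pearson-centered
#' instead (with a warning); constant proteins are an error. When the matrix
#' contains missing values, correlations use pairwise-complete observations.
#'
#' @param x a [protein_matrix] or a numeric matrix with variables in rows.
#' @return symmetric correlation matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @export
bicor_matrix <- function(x) {
  v <- if (inherits(x, "protein_matrix")) x$values else as.matrix(x)
  if (ncol(v) < 4) stopf("bicor requires at least 4 samples")
  if (anyNA(v)) return(bicor_matrix_pairwise(v))
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    stopf("constant protein(s): %s",
          paste(head(rownames(v)[sds == 0], 10), collapse = ", "))
  mads <- apply(v, 1, stats::mad, constant = 1)
  fb <- mads == 0
  if (any(fb))
    warning(sprintf("%d protein(s) with zero mad fall back to Pearson: %s",
                    sum(fb), paste(head(rownames(v)[fb], 5), collapse = ", ")),
            call. = FALSE)
  xt <- t(vapply(seq_len(nrow(v)),
                 function(i) bicor_transform(v[i, ], fb[i]),
                 numeric(ncol(v))))
  xt <- xt / sqrt(rowSums(xt^2))
  r <- tcrossprod(xt)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(v), rownames(v))
  r
}

# pairwise-complete slow path for matrices with missing cells
bicor_matrix_pairwise <- function(v) {
  n <- nrow(v)
  r <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r[i, j] <- r[j, i] <- bicor_pair(v[i, ], v[j, ])
    }
  }
  dimnames(r) <- list(rownames(v), rownames(v))
  r
}
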