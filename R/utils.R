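#' @importFrom stats median mad sd cor pf pt ptukey phyper p.adjust quantile
#'   kruskal.test cutree hclust as.dist rnorm runif rbinom rpois rlnorm
#'   complete.cases setNames
#' @importFrom utils head write.table read.delim
NULL

# internal logging: terse stderr messages, suppressible via option
wp_log <- function(...) {
  if (isTRUE(getOption("wpcna.quiet", FALSE))) return(invisible(NULL))
  message("[wpcna] ", sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scoped RNG: run code with a fixed seed, restore caller's RNG state after
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# two-sided p for a correlation via the t transform, df = n - 2
cor_pvalue <- function(r, n) {
  r[] <- pmin(1, pmax(-1, r))
  df <- n - 2
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p
}
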