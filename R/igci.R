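# Entropy-based information-geometric causal inference (IGCI) with the
# recursive median-partitioning (kDP) entropy estimator, and the rule
# that masks RCCM links under strong/instantaneous coupling.

# One-sample Kolmogorov-Smirnov uniformity check on a sorted sample
# rescaled to [0, 1]; rejects when sqrt(n) * D exceeds the asymptotic
# critical value sqrt(-log(alpha/2)/2).
ks_uniform_reject <- function(u_sorted, alpha) {
  n <- length(u_sorted)
  k <- seq_len(n)
  d <- max(k / n - u_sorted, u_sorted - (k - 1) / n)
  sqrt(n) * d > sqrt(-0.5 * log(alpha / 2))
}

#' kDP differential entropy estimator
#'
#' Estimates differential entropy (in nats) by recursive median-split
#' partitioning: a cell is split at its sample median while a
#' Kolmogorov-Smirnov uniformity test on the cell rejects at level
#' `alpha` and the cell still holds more than `min_cell` points. The
#' estimate is the partition plug-in
#' \eqn{\hat H = \sum_c (n_c/n)\,\log(n\,w_c/n_c)} with \eqn{w_c} the
#' cell width.
#'
#' @param x numeric sample (length >= 8, non-constant).
#' @param min_cell minimum cell occupancy allowed to split further.
#' @param alpha level of the within-cell uniformity test.
#' @return entropy estimate in nats.
#' @examples
#' kdp_entropy(runif(2000))          # close to 0
#' kdp_entropy(rnorm(2000))          # close to 0.5 * log(2 * pi * exp(1))
#' @export
kdp_entropy <- function(x, min_cell = 8, alpha = 0.05) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("kdp_entropy needs at least 8 finite samples")
  x <- sort(x)
  lo0 <- x[1L]; hi0 <- x[n]
  if (hi0 <= lo0)
    stop("degenerate (constant) sample: differential entropy undefined")
  h <- 0
  # iterative traversal of the partition tree
  stack <- list(list(i = 1L, j = n, lo = lo0, hi = hi0))
  while (length(stack) > 0L) {
    cell <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nc <- cell$j - cell$i + 1L
    width <- cell$hi - cell$lo
    split <- FALSE
    if (nc > min_cell && width > 0) {
      u <- (x[cell$i:cell$j] - cell$lo) / width
      if (ks_uniform_reject(u, alpha)) {
        m <- nc %/% 2L
        b <- (x[cell$i + m - 1L] + x[cell$i + m]) / 2
        if (b > cell$lo && b < cell$hi) {
          stack[[length(stack) + 1L]] <-
            list(i = cell$i, j = cell$i + m - 1L, lo = cell$lo, hi = b)
          stack[[length(stack) + 1L]] <-
            list(i = cell$i + m, j = cell$j, lo = b, hi = cell$hi)
          split <- TRUE
        }
      }
    }
    if (!split) h <- h + (nc / n) * log(n * width / nc)
  }
  h
}

#' Entropy-based IGCI score for a cause-effect pair
#'
#' Under a (near-)deterministic invertible mechanism Y = f(X), the
#' effect's distribution is the more "ordered" one: IGCI infers X -> Y
#' whenever H(P_X) > H(P_Y). Both variables are rescaled to \[0, 1\]
#' (uniform reference measure) before entropy estimation, and the score
#' is \eqn{\hat C_{X\to Y} = \hat H(P_Y) - \hat H(P_X)}: X -> Y when
#' the score is below `-epsilon`, Y -> X above `+epsilon`, undecided in
#' between.
#'
#' @param x,y equal-length paired samples (both non-constant). `NA`s are
#'   dropped pairwise.
#' @param epsilon decision threshold on |score| in nats (default 0.2).
#' @param labels optional `c(x = , y = )` variable names.
#' @param ... passed to [kdp_entropy()].
#' @return object of class `igci`: `entropy_x`, `entropy_y`, `score`,
#'   `direction` (`"x->y"`, `"y->x"` or `"undecided"`), `epsilon`.
#' @examples
#' x <- runif(4000)
#' igci(x, x^2)   # infers x -> y; score close to log(2) - 1
#' @export
igci <- function(x, y, epsilon = 0.2, labels = NULL, ...) {
  if (inherits(x, "ccm_series")) x <- x$values
  if (inherits(y, "ccm_series")) y <- y$values
  if (length(x) != length(y))
    stop("x and y must be equal-length paired samples")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  rescale01 <- function(v) {
    r <- range(v)
    if (r[2L] <= r[1L])
      stop("degenerate (constant) sample: IGCI undefined")
    (v - r[1L]) / (r[2L] - r[1L])
  }
  hx <- kdp_entropy(rescale01(x), ...)
  hy <- kdp_entropy(rescale01(y), ...)
  score <- hy - hx
  direction <- if (score < -epsilon) "x->y"
               else if (score > epsilon) "y->x"
               else "undecided"
  structure(list(entropy_x = hx, entropy_y = hy, score = score,
                 direction = direction, epsilon = epsilon,
                 labels = labels),
            class = "igci")
}

#' @export
print.igci <- function(x, ...) {
  nm <- if (!is.null(x$labels)) x$labels else c(x = "x", y = "y")
  dir <- switch(x$direction,
                "x->y" = paste(nm[1L], "->", nm[2L]),
                "y->x" = paste(nm[2L], "->", nm[1L]),
                "undecided")
  cat(sprintf(
    "IGCI: H(%s) = %.3f, H(%s) = %.3f nats; score = %.3f (eps = %.2f) => %s\n",
    nm[1L], x$entropy_x, nm[2L], x$entropy_y, x$score, x$epsilon, dir))
  invisible(x)
}

#' Entropy diagnostics as a data frame (for CSV export)
#'
#' @param x an `igci` object.
#' @param ... unused.
#' @export
as.data.frame.igci <- function(x, ...) {
  data.frame(entropy_x = x$entropy_x, entropy_y = x$entropy_y,
             delta_h = x$score, direction = x$direction)
}

#' Mask an RCCM decision with the IGCI score
#'
#' Strong, effectively instantaneous couplings let CCM detect links in
#' both directions. The mask removes an RCCM link when two conditions
#' hold: a non-negligible entropy difference (|score| > epsilon) and an
#' instantaneous or delayed optimal lag (t_p <= 0), *and* the IGCI
#' direction contradicts the RCCM direction. Links with t_p > 0 are
#' already rejected by the lag rule; links with |score| <= epsilon stand
#' as RCCM found them.
#'
#' @param rccm an [rccm()] decision for the direction cause -> effect.
#' @param igci an [igci()] result computed with `x` = the same cause and
#'   `y` = the same effect (checked via labels when both carry them).
#' @return object of class `masked_decision`: the two inputs plus
#'   `final` (`"kept"`, `"masked"` or `"rejected_by_lag"`), `reason`,
#'   and `link` (`TRUE` when the final kept link is also convergent).
#' @export
mask_rccm <- function(rccm, igci) {
  stopifnot(inherits(rccm, "rccm"), inherits(igci, "igci"))
  if (!is.null(rccm$direction) && !is.null(igci$labels)) {
    if (!setequal(rccm$direction, igci$labels))
      stop("pairing error: RCCM and IGCI results are for different variable pairs")
    flipped <- igci$labels[1L] != rccm$direction[1L]
  } else {
    flipped <- FALSE  # assume igci x = rccm cause
  }
  igci_dir <- igci$direction
  if (flipped && igci_dir != "undecided")
    igci_dir <- if (igci_dir == "x->y") "y->x" else "x->y"
  tp <- rccm$optimal_lag
  if (tp > 0L) {
    final <- "rejected_by_lag"; reason <- "optimal lag positive"
  } else if (abs(igci$score) > igci$epsilon) {
    if (igci_dir == "x->y") {
      final <- "kept"; reason <- "igci agrees with rccm direction"
    } else {
      final <- "masked"; reason <- "igci contradicts rccm direction"
    }
  } else {
    final <- "kept"; reason <- "igci undecided; rccm decision stands"
  }
  structure(list(rccm = rccm, igci = igci, final = final, reason = reason,
                 link = final == "kept" && isTRUE(rccm$convergent)),
            class = "masked_decision")
}

#' @export
print.masked_decision <- function(x, ...) {
  dir <- if (!is.null(x$rccm$direction))
    paste(x$rccm$direction[1L], "->", x$rccm$direction[2L])
    else "cause -> effect"
  cat(sprintf("Masked decision (%s): %s [%s]\n", dir, x$final, x$reason))
  cat(sprintf("  rho~ = %.3f, t_p = %d, convergent = %s, IGCI score = %.3f\n",
              x$rccm$robust_skill, x$rccm$optimal_lag, x$rccm$convergent,
              x$igci$score))
  invisible(x)
}
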