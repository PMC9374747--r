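#' Two-tailed Welch's t-test
#'
#' Unequal-variance two-sample t-test with Satterthwaite degrees of freedom.
#' Degenerate inputs follow a strict contract: if both groups are constant
#' with equal means the p-value is 1 by convention; if both are constant
#' with unequal means (or a group has fewer than 2 observations) the result
#' is undefined (NA) and flagged, never forced to 0.
#'
#' @param a,b numeric replicate vectors (NAs dropped).
#' @return list(t, df, p, flag) where flag is "" or a reason the test is
#'   undefined.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                flag = "fewer than 2 replicates"))
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, flag = ""))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                flag = "zero variance, unequal means"))
  }
  se2 <- va / length(a) + vb / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  list(t = tt, df = df, p = max(p, .Machine$double.xmin), flag = "")
}

# Vectorised Welch test over matrix rows (molecules x replicates).
# Returns a p-value per row; degenerate rows follow the welch_test contract.
row_welch <- function(A, B) {
  na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  va <- rowSums((A - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((B - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / pmax(na - 1, 1) + (vb / nb)^2 / pmax(nb - 1, 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[va == 0 & vb == 0 & ma == mb] <- 1
  p[(va == 0 & vb == 0 & ma != mb) | na < 2 | nb < 2] <- NA_real_
  unname(p)
}

.count_methods <- new.env(parent = emptyenv())

#' Registered count-test methods
#' @return character vector of method names.
#' @export
count_methods <- function() sort(ls(.count_methods))

#' Register a two-group count-test method
#'
#' The gene layer's differential test is pluggable: the study used an
#' external negative-binomial package, which is out of scope here, so a
#' documented default ("log_welch") is provided and alternatives can be
#' registered under a name.
#' @param name method name.
#' @param fun function(a, b) returning a p-value.
#' @export
register_count_method <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .count_methods)
  invisible(name)
}

#' Two-group test for count replicates
#'
#' Default method "log_welch": Welch's t-test on log2(count + 1), after
#' optional library-size scaling of each observation to the median library
#' total. Groups that are all zero on both sides give p = 1.
#'
#' @param a,b non-negative count vectors.
#' @param method registered method name (default "log_welch").
#' @param lib_a,lib_b optional library sizes per replicate; when supplied,
#'   counts are scaled by median(all libraries)/library before testing.
#' @return a p-value.
#' @export
count_test <- function(a, b, method = "log_welch", lib_a = NULL, lib_b = NULL) {
  if (any(c(a, b) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (!is.null(lib_a) || !is.null(lib_b)) {
    libs <- c(lib_a, lib_b)
    target <- stats::median(libs)
    if (!is.null(lib_a)) a <- a * (target / lib_a)
    if (!is.null(lib_b)) b <- b * (target / lib_b)
  }
  if (all(a == 0, na.rm = TRUE) && all(b == 0, na.rm = TRUE)) return(1)
  fun <- get0(method, envir = .count_methods)
  if (is.null(fun)) stop("unknown count-test method '", method, "'")
  fun(a, b)
}

#' Storey q-values
#'
#' False-discovery-rate q-values with an estimated null proportion pi0. By
#' default pi0 is estimated on the lambda grid 0.05..0.95 (step 0.05) with a
#' cubic smoothing spline evaluated at the largest lambda, clamped to
#' (0, 1]; \code{fixed_lambda} switches to the single-lambda estimate
#' pi0 = #(p > lambda) / (m (1 - lambda)) for exact unit checks. With
#' pi0 = 1 the result is exactly the Benjamini-Hochberg step-up adjustment.
#'
#' @param p vector of p-values in [0, 1] (NAs allowed, returned as NA).
#' @param lambda grid for the smoother estimate.
#' @param fixed_lambda single lambda overriding the smoother.
#' @param pi0 optional fixed null proportion overriding estimation.
#' @return q-values in input order, each in [0, 1].
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           fixed_lambda = NULL, pi0 = NULL) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m == 0L) return(q)
  if (is.null(pi0)) {
    if (!is.null(fixed_lambda)) {
      pi0 <- sum(pp > fixed_lambda) / (m * (1 - fixed_lambda))
    } else {
      pi0_l <- vapply(lambda, function(l) sum(pp > l) / (m * (1 - l)), 0)
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    }
  }
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  o <- order(pp)
  qs <- pi0 * m * pp[o] / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  tmp <- rep(NA_real_, m)
  tmp[o] <- qs
  q[ok] <- tmp
  attr(q, "pi0") <- pi0
  q
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1), in input order.
#' @param p vector of p-values in [0, 1] (NAs allowed).
#' @return adjusted q-values.
#' @export
bh_qvalues <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
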