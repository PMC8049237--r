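# Saltelli design and Sobol' indices ---------------------------------------------

halton_primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
                   53, 59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107,
                   109, 113, 127, 131, 137, 139, 149, 151, 157, 163, 167,
                   173)

# randomised low-discrepancy sample on [0,1)^dim: Halton radical-inverse
# sequence with a Cranley-Patterson rotation drawn from the seeded RNG
halton_shifted <- function(n, dim, shift) {
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- halton_primes[d]
    i <- seq_len(n)
    x <- numeric(n)
    f <- 1 / b
    while (any(i > 0)) {
      x <- x + (i %% b) * f
      i <- i %/% b
      f <- f / b
    }
    out[, d] <- (x + shift[d]) %% 1
  }
  out
}

#' Saltelli cross-sampling design
#'
#' Builds the radial design of exactly `(2D + 2) * N` model evaluation
#' points: two base matrices A and B drawn from a randomised low-discrepancy
#' (quasi-random) sequence over the input ranges, plus, for every input i,
#' A with column i taken from B (AB_i) and B with column i taken from A
#' (BA_i). Beyond 20 inputs the base sample falls back to plain
#' pseudo-random uniforms.
#'
#' @param ranges numeric matrix `D x 2` (min, max per input) or a data frame
#'   with columns `min` and `max`.
#' @param N base sample size per matrix.
#' @param seed integer RNG seed.
#' @return list with matrices `A`, `B`, lists `AB`, `BA`, the stacked
#'   `design` (`(2D+2)*N x D`), and `N`, `D`.
#' @export
saltelli_design <- function(ranges, N, seed = 1L) {
  if (is.data.frame(ranges)) ranges <- cbind(ranges$min, ranges$max)
  ranges <- as.matrix(ranges)
  D <- nrow(ranges)
  stopifnot(ncol(ranges) == 2, all(is.finite(ranges)), N >= 2)
  set.seed(seed)
  base <- if (2L * D <= length(halton_primes)) {
    halton_shifted(N, 2L * D, stats::runif(2L * D))
  } else {
    matrix(stats::runif(N * 2L * D), N, 2L * D)
  }
  scale_cols <- function(U) {
    sweep(sweep(U, 2, ranges[, 2] - ranges[, 1], `*`), 2, ranges[, 1], `+`)
  }
  A <- scale_cols(base[, seq_len(D), drop = FALSE])
  B <- scale_cols(base[, D + seq_len(D), drop = FALSE])
  AB <- purrr::map(seq_len(D), function(i) { M <- A; M[, i] <- B[, i]; M })
  BA <- purrr::map(seq_len(D), function(i) { M <- B; M[, i] <- A[, i]; M })
  design <- do.call(rbind, c(list(A, B), AB, BA))
  list(A = A, B = B, AB = AB, BA = BA, design = design, N = N, D = D)
}

#' Sobol' global sensitivity indices by the Saltelli method
#'
#' Evaluates the model on a [saltelli_design()] and estimates first-order
#' indices S1 (Saltelli 2010 estimator, averaged over the AB and BA radial
#' blocks) and total effects ST (Jansen estimator). The "multifactorial"
#' share is `max(0, 1 - sum(S1))`: output variance not attributable to any
#' single input alone. Deterministic for a fixed seed.
#'
#' @param model a fitted [gpe_fit()] / [train_gpes_loo()] emulator, or a
#'   function mapping an `m x D` matrix to a numeric vector.
#' @param ranges input ranges as in [saltelli_design()].
#' @param N base sample size (>= 64; the number of model evaluations is
#'   `(2D + 2) * N`).
#' @param seed integer RNG seed.
#' @param input_names optional names for the D inputs.
#' @return object of class `sobol_result`.
#' @export
sobol_saltelli <- function(model, ranges, N = 1000, seed = 1L,
                           input_names = NULL) {
  stopifnot(N >= 64)
  f <- if (is.function(model)) {
    model
  } else if (inherits(model, "gpe_loo")) {
    function(Xm) predict(model$model, Xm)$.pred
  } else if (inherits(model, "gpe")) {
    function(Xm) predict(model, Xm)$.pred
  } else {
    stop("model must be a function, gpe or gpe_loo", call. = FALSE)
  }
  des <- saltelli_design(ranges, N, seed)
  D <- des$D
  fall <- f(des$design)
  if (any(!is.finite(fall))) {
    bad <- which(!is.finite(fall))[1]
    stop("non-finite model output at design point ", bad, ": (",
         paste(signif(des$design[bad, ], 4), collapse = ", "), ")",
         call. = FALSE)
  }
  idx <- function(block) (block - 1L) * des$N + seq_len(des$N)
  fA <- fall[idx(1L)]
  fB <- fall[idx(2L)]
  V <- stats::var(c(fA, fB))
  s1 <- st <- numeric(D)
  for (i in seq_len(D)) {
    fABi <- fall[idx(2L + i)]
    fBAi <- fall[idx(2L + D + i)]
    s1[i] <- 0.5 * (mean(fB * (fABi - fA)) + mean(fA * (fBAi - fB))) / V
    st[i] <- 0.25 * (mean((fA - fABi)^2) + mean((fB - fBAi)^2)) / V
  }
  nms <- input_names %||% paste0("x", seq_len(D))
  structure(list(
    indices = tibble::tibble(input = nms, S1 = s1, ST = st),
    multifactorial = max(0, 1 - sum(s1)),
    N = N, D = D, seed = seed,
    n_evaluations = (2L * D + 2L) * N), class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("sobol_result: D =", x$D, ", N =", x$N, "(",
      x$n_evaluations, "model evaluations )\n")
  print(x$indices, n = min(nrow(x$indices), 10))
  cat("multifactorial share:", signif(x$multifactorial, 4), "\n")
  invisible(x)
}

#' @export
tidy.sobol_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$indices, share = .data$S1),
    tibble::tibble(input = "multifactorial", S1 = NA_real_, ST = NA_real_,
                   share = x$multifactorial))
}

#' @export
glance.sobol_result <- function(x, ...) {
  tibble::tibble(D = x$D, N = x$N, n_evaluations = x$n_evaluations,
                 sum_S1 = sum(x$indices$S1),
                 multifactorial = x$multifactorial)
}
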