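# Variance-based global sensitivity analysis: Sobol' quasi-random
# sampling in Saltelli's radial design, first- and total-order index
# estimators, and the driver that maps hepatic resistance scale factors
# to cardiac outputs.

# ---------------------------------------------------------------------
# Sobol' low-discrepancy sequence (Joe & Kuo direction numbers, d <= 10)
# ---------------------------------------------------------------------

# degree s, polynomial coefficient a, initial direction integers m
.sobol_dirs <- list(
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19))
)

# 30 bits keeps every direction integer and digital shift strictly below
# .Machine$integer.max while leaving ~1e-9 resolution
.SOBOL_BITS <- 30

# Direction integers v_1..v_bits (scaled to 2^.SOBOL_BITS) for one dim.
.sobol_v <- function(dim) {
  bits <- .SOBOL_BITS
  v <- integer(bits)
  if (dim == 1) {
    for (k in seq_len(bits)) v[k] <- bitwShiftL(1L, bits - k)
    return(v)
  }
  d <- .sobol_dirs[[dim - 1]]
  s <- d$s
  mm <- as.integer(d$m)
  a <- d$a
  m <- integer(bits)
  m[seq_len(s)] <- mm
  if (bits > s) {
    for (k in (s + 1):bits) {
      mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
      for (j in seq_len(s - 1)) {
        if (bitwAnd(bitwShiftR(a, s - 1 - j), 1L) == 1L)
          mk <- bitwXor(mk, bitwShiftL(m[k - j], j))
      }
      m[k] <- mk
    }
  }
  for (k in seq_len(bits)) v[k] <- bitwShiftL(m[k], bits - k)
  v
}

#' Sobol' quasi-random sequence
#'
#' Gray-code Sobol' sequence in up to 10 dimensions using Joe-Kuo
#' direction numbers, optionally randomized by a seeded digital shift
#' (XOR of every point with one random binary fraction per dimension),
#' which preserves the low-discrepancy structure.
#'
#' @param n Number of points.
#' @param d Number of dimensions, `<= 10`.
#' @param seed Integer; `NULL` for the plain (unshifted) sequence.
#' @return An `n x d` matrix of points in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d, seed = NULL) {
  if (d < 1 || d > length(.sobol_dirs) + 1)
    stop("sobol_sequence: d must be between 1 and ", length(.sobol_dirs) + 1)
  denom <- 2^.SOBOL_BITS
  V <- vapply(seq_len(d), .sobol_v, integer(.SOBOL_BITS))
  X <- matrix(0L, n, d)
  x <- integer(d)
  # point 0 is the origin; subsequent points flip the bit given by the
  # index of the lowest zero bit of i-1 (Gray-code construction)
  if (n > 1) {
    for (i in 2:n) {
      c1 <- 1L
      value <- i - 2L
      while (bitwAnd(value, 1L) == 1L) {
        value <- bitwShiftR(value, 1L)
        c1 <- c1 + 1L
      }
      x <- bitwXor(x, V[c1, ])
      X[i, ] <- x
    }
  }
  if (!is.null(seed)) {
    set.seed(seed)
    shift <- as.integer(floor(stats::runif(d) * denom))
    for (j in seq_len(d)) X[, j] <- bitwXor(X[, j], shift[j])
  }
  X / denom
}

# ---------------------------------------------------------------------
# Saltelli design and Sobol' index estimators
# ---------------------------------------------------------------------

#' Sensitivity design over hepatic resistance scale factors
#'
#' @param parameters Names of the factors; default the four hepatic
#'   resistances, with `R_hv` acting jointly on the three hepatic veins.
#' @param scale_bounds Length-2 interval of the scale factors applied to
#'   the baseline values; default `c(0.5, 10)`.
#' @param N Base sample count of the Saltelli design; total model
#'   evaluations are `N * (2K + 2)`.  Default 500 (5000 evaluations for
#'   K = 4).  A power of two is recommended for the underlying Sobol'
#'   sequence.
#' @param seed Integer seed (digital shift of the quasi-random sequence
#'   and the bootstrap).
#' @param outputs Output names to analyse; default CO, MAP, SW.
#' @param log_scale Sample the scales log-uniformly instead of uniformly
#'   on the interval; default `FALSE`.
#' @return An object of class `sensitivity_design`.
#' @export
sensitivity_design <- function(parameters = c("R_pv_d", "R_ha_d", "R_hs", "R_hv"),
                               scale_bounds = c(0.5, 10), N = 500, seed = 1,
                               outputs = c("CO", "MAP", "SW"),
                               log_scale = FALSE) {
  if (length(scale_bounds) != 2 || scale_bounds[1] > scale_bounds[2])
    stop("sensitivity_design: scale_bounds must be an interval")
  structure(list(parameters = parameters, scale_bounds = scale_bounds,
                 N = as.integer(N), seed = seed, outputs = outputs,
                 log_scale = log_scale),
            class = "sensitivity_design")
}

#' Saltelli sample matrix
#'
#' Builds the `N * (2K + 2)`-row design: base matrices `A` and `B` from
#' a 2K-dimensional Sobol' sequence, then the radial matrices `AB_j` (A
#' with column j from B) and `BA_j` (B with column j from A).  Rows are
#' scale factors within `scale_bounds`.
#'
#' @param d A [sensitivity_design()].
#' @return Matrix with `N * (2K + 2)` rows and K named columns, with
#'   attribute `block` labelling each row (`"A"`, `"B"`, `"AB<j>"`,
#'   `"BA<j>"`).
#' @export
saltelli_matrix <- function(d) {
  stopifnot(inherits(d, "sensitivity_design"))
  K <- length(d$parameters)
  N <- d$N
  if (bitwAnd(N, N - 1L) != 0L)
    warning("saltelli_matrix: N is not a power of two; ",
            "the Sobol' sequence is better balanced when it is")
  U <- sobol_sequence(N, 2 * K, seed = d$seed)
  lo <- d$scale_bounds[1]; hi <- d$scale_bounds[2]
  tr <- if (d$log_scale) {
    function(u) exp(log(lo) + u * (log(hi) - log(lo)))
  } else {
    function(u) lo + u * (hi - lo)
  }
  A <- tr(U[, seq_len(K), drop = FALSE])
  B <- tr(U[, K + seq_len(K), drop = FALSE])
  blocks <- list(A = A, B = B)
  for (j in seq_len(K)) {
    ABj <- A; ABj[, j] <- B[, j]
    blocks[[paste0("AB", j)]] <- ABj
  }
  for (j in seq_len(K)) {
    BAj <- B; BAj[, j] <- A[, j]
    blocks[[paste0("BA", j)]] <- BAj
  }
  X <- do.call(rbind, blocks)
  colnames(X) <- d$parameters
  attr(X, "block") <- rep(names(blocks), each = N)
  attr(X, "N") <- N
  attr(X, "K") <- K
  X
}

#' First- and total-order Sobol' indices from Saltelli blocks
#'
#' Estimates, for each factor j, the first-order index
#' `S_j = V(E(y | x_j)) / V(y)` and the total-order index
#' `ST_j = 1 - V(E(y | x_-j)) / V(y)` with Saltelli's `S` estimator and
#' Jansen's `ST` estimator.  Both radial block families (`AB_j`, `BA_j`)
#' are used and averaged.  Uncertainty is quantified by a row bootstrap.
#'
#' @param y Numeric vector of model outputs, ordered as the rows of
#'   [saltelli_matrix()].
#' @param X The design matrix the outputs were computed on (for block
#'   structure), or a list with attributes `N` and `K`.
#' @param n_boot Bootstrap replicates for the 95% half-widths.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `sobol_result`: data frame with columns
#'   `parameter`, `S`, `ST`, `S_ci`, `ST_ci`.
#' @export
sobol_indices <- function(y, X, n_boot = 100, seed = 1) {
  N <- attr(X, "N"); K <- attr(X, "K")
  if (is.null(N) || is.null(K)) stop("sobol_indices: X lacks design attributes")
  if (length(y) != N * (2 * K + 2))
    stop("sobol_indices: y length does not match the design")
  if (any(!is.finite(y))) stop("sobol_indices: non-finite outputs")
  yA <- y[seq_len(N)]
  yB <- y[N + seq_len(N)]
  yAB <- lapply(seq_len(K), function(j) y[(1 + j) * N + seq_len(N)])
  yBA <- lapply(seq_len(K), function(j) y[(1 + K + j) * N + seq_len(N)])

  est <- function(idx) {
    a <- yA[idx]; b <- yB[idx]
    mu <- mean(c(a, b))
    V <- stats::var(c(a, b))
    if (V <= 0) stop("sobol_indices: zero output variance; indices undefined")
    # centering the multiplier removes the E[y]*E[y_ABj - y_A] noise term
    # from the first-order estimator without changing its expectation
    ac <- a - mu; bc <- b - mu
    S <- ST <- numeric(K)
    for (j in seq_len(K)) {
      abj <- yAB[[j]][idx]; baj <- yBA[[j]][idx]
      # Saltelli 2010 first-order estimator, averaged over both families
      S[j] <- 0.5 * (mean(bc * (abj - a)) + mean(ac * (baj - b))) / V
      # Jansen total-order estimator, averaged over both families
      ST[j] <- 0.5 * (mean((a - abj)^2) + mean((b - baj)^2)) / (2 * V)
    }
    c(S, ST)
  }
  point <- est(seq_len(N))
  set.seed(seed)
  boot <- replicate(n_boot, est(sample.int(N, N, replace = TRUE)))
  half <- apply(boot, 1, function(v) diff(stats::quantile(v, c(0.025, 0.975))) / 2)
  parameters <- colnames(X)
  if (is.null(parameters)) parameters <- paste0("x", seq_len(K))
  structure(data.frame(parameter = parameters,
                       S = point[seq_len(K)], ST = point[K + seq_len(K)],
                       S_ci = half[seq_len(K)], ST_ci = half[K + seq_len(K)]),
            class = c("sobol_result", "data.frame"))
}

#' Run the hepatic sensitivity experiment
#'
#' Generates the Saltelli design over scale factors of the four hepatic
#' resistances (`R_pv_d`, `R_ha_d`, `R_hs`, and `R_hv` scaling the three
#' hepatic veins jointly), simulates every sample to periodic steady
#' state, records cardiac output (L/min), mean aortic pressure (mmHg)
#' and stroke work (mmHg.mL), and estimates Sobol' indices per output.
#'
#' @param base The calibrated [circulation_model()].
#' @param d A [sensitivity_design()].
#' @param settings [simulation_settings()] per evaluation.
#' @param progress Print a progress line every 500 evaluations.
#' @return List with `indices` (named list of `sobol_result` per output),
#'   `evaluations` (data frame of scales and outputs), `n_failed`.
#'   Failed rows abort the analysis if they exceed 1% of the design.
#' @export
run_sensitivity <- function(base, d = sensitivity_design(),
                            settings = simulation_settings(),
                            progress = FALSE) {
  stopifnot(inherits(base, "circulation_model"), inherits(d, "sensitivity_design"))
  X <- saltelli_matrix(d)
  init <- default_initial_state(base)
  n <- nrow(X)
  out <- matrix(NA_real_, n, length(d$outputs),
                dimnames = list(NULL, d$outputs))
  for (i in seq_len(n)) {
    m <- base
    sc <- X[i, ]
    m$hepatic$R_pv_d <- m$hepatic$R_pv_d * sc[["R_pv_d"]]
    m$hepatic$R_ha_d <- m$hepatic$R_ha_d * sc[["R_ha_d"]]
    m$hepatic$R_hs <- m$hepatic$R_hs * sc[["R_hs"]]
    for (f in c("R_lhv", "R_mhv", "R_rhv"))
      m$hepatic[[f]] <- m$hepatic[[f]] * sc[["R_hv"]]
    mm <- tryCatch(
      suppressWarnings(compute_cardiac_metrics(run_simulation(m, settings, init))),
      error = function(e) NULL)
    if (!is.null(mm))
      out[i, ] <- vapply(d$outputs, function(o) mm[[o]], numeric(1))
    if (progress && i %% 500 == 0)
      message(sprintf("run_sensitivity: %d / %d evaluations", i, n))
  }
  failed <- !stats::complete.cases(out)
  if (sum(failed) > 0.01 * n)
    stop(sprintf("run_sensitivity: %d of %d evaluations failed (> 1%%)",
                 sum(failed), n))
  if (any(failed)) {
    # impute the rare failure with the output column mean so the block
    # structure stays intact; count is reported
    for (j in seq_len(ncol(out)))
      out[failed, j] <- mean(out[!failed, j])
  }
  indices <- lapply(stats::setNames(d$outputs, d$outputs), function(o)
    sobol_indices(out[, o], X, seed = d$seed))
  list(indices = indices,
       evaluations = data.frame(X, out, check.names = FALSE),
       n_failed = sum(failed))
}

#' Write Sobol' indices to CSV
#'
#' One row per output/parameter pair, columns `output, parameter, S, ST,
#' S_ci, ST_ci`.
#'
#' @param res The result of [run_sensitivity()].
#' @param path Output path.
#' @return The data frame written, invisibly.
#' @export
write_sobol_csv <- function(res, path) {
  df <- do.call(rbind, lapply(names(res$indices), function(o)
    cbind(output = o, as.data.frame(res$indices[[o]]))))
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}
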