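# Dirichlet-kernel helpers ---------------------------------------------------

# sin(pi * n * df * u) / sin(pi * df * u), with the removable singularities at
# sin(pi * df * u) = 0 evaluated exactly by direct summation of the n cosines
dirichlet_ratio <- function(u, n, df) {
  den <- sin(pi * df * u)
  out <- sin(pi * n * df * u) / den
  sing <- abs(den) < 1e-4
  if (any(sing)) {
    # sum of n symmetric cosines: exact where the ratio is indeterminate
    k <- seq_len(n)
    out[sing] <- vapply(u[sing], function(ui)
      sum(cos(pi * (2 * k - n - 1) * df * ui)), numeric(1))
  }
  out
}

# one branch of the noiseless cosine-bank output:
# 0.5 * sum_k cos(2 pi f_k u)  for f_k = f1 + k df, k = 1..n
# = 0.5 * D(u) * cos(pi (2 f1 + (n + 1) df) u)  with D the Dirichlet ratio
cosine_branch <- function(u, f1, df, n) {
  den <- sin(pi * df * u)
  val <- 0.5 * sin(pi * n * df * u) / den * cos(pi * (2 * f1 + (n + 1) * df) * u)
  sing <- abs(den) < 1e-4
  if (any(sing)) {
    f <- f1 + seq_len(n) * df
    val[sing] <- vapply(u[sing], function(ui) 0.5 * sum(cos(2 * pi * f * ui)),
                        numeric(1))
  }
  val
}

# Time grids ------------------------------------------------------------------

#' Default evaluation grid around a criterion time
#'
#' Step `min(1 / (20 f2), c / 2000)` resolves the fastest oscillator and the
#' envelope; the window spans `c` plus/minus `half_width_sigmas` times an a
#' priori width estimate `sqrt(sigma_kernel^2 + (level * c)^2)`, where
#' `sigma_kernel` is the noiseless envelope width (as a Gaussian sigma) and
#' `level` the relative memory-noise level.
#'
#' @param bank An [oscillator_bank()] or `ml_bank`.
#' @param criterion Criterion time (s).
#' @param mem_noise A [noise_spec()]; widens the window.
#' @param half_width_sigmas Half-window in units of the width estimate.
#' @return Numeric vector of times (s).
#' @export
default_time_grid <- function(bank, criterion, mem_noise = noise_off(),
                              half_width_sigmas = 6) {
  b <- base_bank(bank)
  step <- min(1 / (20 * b$f2), criterion / 2000)
  sig <- output_sigma_guess(bank, criterion, mem_noise)
  half <- max(half_width_sigmas * sig, 50 * step)
  half <- step * ceiling(half / step)   # keep the criterion on the grid
  seq(criterion - half, criterion + half, by = step)
}

# a priori Gaussian-sigma estimate of the output width
output_sigma_guess <- function(bank, criterion, mem_noise = noise_off()) {
  sig0 <- noiseless_width(base_bank(bank)) / (2 * sqrt(2 * log(2)))
  sqrt(sig0^2 + (mem_noise$level * criterion)^2)
}

# Output functions ------------------------------------------------------------

new_sbf_output <- function(t, value, config) {
  structure(tibble(t = t, value = value), config = config,
            class = c("sbf_output", class(tibble())))
}

#' @export
print.sbf_output <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<sbf_output> %d time points%s\n", nrow(x),
              if (!is.null(cfg$criterion))
                sprintf(", criterion = %g s", cfg$criterion) else ""))
  NextMethod()
}

#' SBF output function by coincidence detection
#'
#' Compares the memorised reference weights at the criterion time with the
#' running weights at every grid time. With `similarity = "dot"` (the
#' default, matching the model's analytic forms) the output is the raw dot
#' product `sum_k w(k, c) w(k, t)`; with `similarity = "cosine_angle"` it is
#' the absolute cosine of the angle between the two vectors, which lies in
#' `[0, 1]` and equals 1 at `t = c` in the noiseless case. Memory noise
#' enters through the reference weights; frequency noise averages the output
#' over `freq_noise$n_samples` complete bank draws, each with its own
#' reference and running weights.
#'
#' @param bank An [oscillator_bank()] or `ml_bank`.
#' @param criterion Criterion time (s).
#' @param t_grid Evaluation times; defaults to [default_time_grid()].
#' @param mem_noise,freq_noise [noise_spec()]s for the stored criterion and
#'   the oscillator frequencies.
#' @param mode Weight mode, `"signed"` or `"positive"`.
#' @param similarity `"dot"` or `"cosine_angle"`.
#' @param normalize Divide weight vectors by their `Norm` (the maximum raw
#'   state) before the dot product. The default `FALSE` matches the
#'   unnormalised analytic sums; widths and slopes are unaffected either way.
#' @param branch `"both"` (default) is the plain dot product of real states,
#'   whose product terms contain both a `t - c` and a mirrored `t + c`
#'   component (the latter re-enters the observation window through the
#'   bank's `1/df` recurrence when criteria approach the timing capacity).
#'   `"retained"` keeps only the physically meaningful `t - c` component by
#'   projecting with the analytic (in-phase plus quadrature) representation
#'   of each oscillator; for a cosine bank this equals the closed-form
#'   retained branch exactly.
#' @param keep_batches See [memory_noise_output()]; enables
#'   [burst_envelope()].
#' @return An `sbf_output` tibble with columns `t`, `value` and a `config`
#'   attribute recording the full provenance.
#' @examples
#' bank <- oscillator_bank(5.5, 11.5, 100)
#' out <- sbf_output(bank, criterion = 10)
#' out[which.max(out$value), ]
#' @export
sbf_output <- function(bank, criterion, t_grid = NULL,
                       mem_noise = noise_off(), freq_noise = noise_off(),
                       mode = c("signed", "positive"),
                       similarity = c("dot", "cosine_angle"),
                       normalize = FALSE, branch = c("both", "retained"),
                       keep_batches = 1L) {
  mode <- match.arg(mode)
  similarity <- match.arg(similarity)
  branch <- match.arg(branch)
  if (branch == "retained" && (similarity != "dot" || normalize))
    abort('branch = "retained" requires similarity = "dot" and normalize = FALSE',
          class = "sbf_usage_error")
  t_grid <- t_grid %||% default_time_grid(bank, criterion, mem_noise)
  b <- base_bank(bank)
  if (length(t_grid) > 1 && max(diff(t_grid)) > 1 / (2 * b$f2))
    warn("time grid is coarser than half the fastest oscillation period")
  n_osc <- n_oscillators(bank)

  criteria <- sample_criteria(criterion, mem_noise)
  n_f <- if (freq_noise$family == "none") 1L else freq_noise$n_samples
  mult <- if (n_f > 1L || freq_noise$family != "none") {
    matrix(sample_multipliers(freq_noise, n_f * n_osc), nrow = n_osc)
  } else NULL

  value <- 0
  batch_values <- NULL
  keep_batches <- min(as.integer(keep_batches), length(criteria))
  for (j in seq_len(n_f)) {
    mj <- if (is.null(mult)) NULL else mult[, j]
    S <- state_matrix(bank, as.numeric(criteria), freq_multipliers = mj)
    run <- state_matrix(bank, t_grid, freq_multipliers = mj)
    if (branch == "retained") {
      Sq <- state_matrix(bank, as.numeric(criteria), freq_multipliers = mj,
                         quadrature = TRUE)
      runq <- state_matrix(bank, t_grid, freq_multipliers = mj,
                           quadrature = TRUE)
      # in-phase plus quadrature projection: only the t - c component
      value <- value +
        (drop(crossprod(run, rowSums(S))) +
           drop(crossprod(runq, rowSums(Sq)))) / 2
    } else {
      value <- value +
        combine_weights(rowSums(S), run, mode, similarity, normalize)
    }
    if (keep_batches > 1L && n_f == 1L && similarity == "dot" && !normalize) {
      grp <- batch_index(length(criteria), keep_batches)
      ref_b <- vapply(seq_len(keep_batches),
                      function(g) rowSums(S[, grp == g, drop = FALSE]),
                      numeric(n_osc))
      batch_values <- crossprod(run, ref_b)
      if (branch == "retained") {
        ref_bq <- vapply(seq_len(keep_batches),
                         function(g) rowSums(Sq[, grp == g, drop = FALSE]),
                         numeric(n_osc))
        batch_values <- (batch_values + crossprod(runq, ref_bq)) / 2
      }
    }
  }
  value <- value / n_f

  out <- new_sbf_output(t_grid, value, config = list(
    bank = b, kind = if (inherits(bank, "ml_bank")) "ml" else "cosine",
    criterion = criterion, mem_noise = mem_noise, freq_noise = freq_noise,
    mode = mode, similarity = similarity, normalize = normalize,
    branch = branch
  ))
  if (!is.null(batch_values)) attr(out, "batch_values") <- batch_values
  out
}

combine_weights <- function(ref_raw, run_raw, mode, similarity, normalize) {
  ref <- ref_raw
  run <- run_raw
  if (normalize || mode == "positive") {
    norm_ref <- max(ref_raw)
    if (norm_ref <= 0) norm_ref <- max(abs(ref_raw))
    norm_run <- apply(run_raw, 2, function(col) {
      m <- max(col); if (m <= 0) max(abs(col)) else m
    })
    ref <- ref_raw / norm_ref
    run <- sweep(run_raw, 2, norm_run, "/")
    if (mode == "positive") {
      ref <- (ref + 1) / 2
      run <- (run + 1) / 2
    }
  }
  dots <- drop(crossprod(run, ref))
  if (similarity == "dot") return(dots)
  abs(dots) / (sqrt(sum(ref^2)) * sqrt(colSums(run^2)))
}

#' Closed-form noiseless cosine output
#'
#' The exact closed form of the noiseless cosine-bank dot-product output:
#' two mirrored Dirichlet-kernel branches centred at `t = +c` and `t = -c`,
#' each `0.5 * sin(pi n df u) cos(pi (2 f1 + (n + 1) df) u) / sin(pi df u)`
#' with `u = t -/+ c`; removable singularities are evaluated exactly. Equals
#' the direct double sum over oscillators at every time point.
#'
#' @param bank An [oscillator_bank()].
#' @param criterion Criterion time (s).
#' @param t_grid Evaluation times; defaults to [default_time_grid()].
#' @return An `sbf_output` tibble.
#' @export
closed_form_output <- function(bank, criterion, t_grid = NULL) {
  stopifnot(inherits(bank, "oscillator_bank"))
  t_grid <- t_grid %||% default_time_grid(bank, criterion)
  u1 <- t_grid - criterion
  u2 <- t_grid + criterion
  value <- cosine_branch(u1, bank$f1, bank$df, bank$n_osc) +
    cosine_branch(u2, bank$f1, bank$df, bank$n_osc)
  new_sbf_output(t_grid, value, config = list(
    bank = bank, kind = "cosine", criterion = criterion,
    mem_noise = noise_off(), freq_noise = noise_off(),
    mode = "signed", similarity = "dot", normalize = FALSE,
    closed_form = TRUE
  ))
}

#' Retained-branch output under criterion-time (memory) noise
#'
#' The physically realisable branch of the cosine-bank output, summed over
#' the `Nc` sampled criterion times:
#' `output(t) = 0.5 * sum_j sum_k cos(2 pi f_k (t - c_j))`, evaluated through
#' the per-sample Dirichlet closed form. With no noise (a single sample equal
#' to `c`) it reduces to the noiseless retained branch, whose value at
#' `t -> c` approaches `n_osc / 2`.
#'
#' @param bank An [oscillator_bank()].
#' @param criterion Criterion time (s).
#' @param t_grid Evaluation times; defaults to [default_time_grid()].
#' @param mem_noise A [noise_spec()] for the stored criterion.
#' @param criteria Optional explicit vector of sampled criterion times,
#'   overriding `mem_noise` (used for enumerated-sample checks).
#' @param keep_batches When > 1, the sampled criteria are split into this
#'   many consecutive batches and the per-batch partial sums are attached as
#'   a `batch_values` matrix attribute, enabling the low-variance amplitude
#'   envelope of [burst_envelope()]. The `value` column is unaffected.
#' @return An `sbf_output` tibble.
#' @examples
#' bank <- oscillator_bank(5.5, 11.5, 1000)
#' out <- memory_noise_output(bank, 30)   # noiseless retained branch
#' max(out$value)                         # ~ n_osc / 2
#' @export
memory_noise_output <- function(bank, criterion, t_grid = NULL,
                                mem_noise = noise_off(), criteria = NULL,
                                keep_batches = 1L) {
  stopifnot(inherits(bank, "oscillator_bank"))
  t_grid <- t_grid %||% default_time_grid(bank, criterion, mem_noise)
  criteria <- criteria %||% as.numeric(sample_criteria(criterion, mem_noise))
  if (length(criteria) < 1)
    abort("at least one criterion sample is required",
          class = "sbf_config_error")
  u <- outer(t_grid, criteria, "-")
  v <- cosine_branch(as.numeric(u), bank$f1, bank$df, bank$n_osc)
  dim(v) <- dim(u)
  out <- new_sbf_output(t_grid, rowSums(v), config = list(
    bank = bank, kind = "cosine", criterion = criterion,
    mem_noise = mem_noise, freq_noise = noise_off(),
    mode = "signed", similarity = "dot", normalize = FALSE,
    retained_branch = TRUE, n_criteria = length(criteria)
  ))
  keep_batches <- min(as.integer(keep_batches), length(criteria))
  if (keep_batches > 1L) {
    grp <- batch_index(length(criteria), keep_batches)
    bm <- vapply(seq_len(keep_batches),
                 function(b) rowSums(v[, grp == b, drop = FALSE]),
                 numeric(length(t_grid)))
    attr(out, "batch_values") <- bm
  }
  out
}

# consecutive, near-equal batch assignment 1..n -> 1..b
batch_index <- function(n, b) {
  rep(seq_len(b), length.out = b * ceiling(n / b))[seq_len(n)] |> sort()
}
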