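#' Linear tumor-evolution model parameters
#'
#' The model assumes occasional driver mutations sweep to fixation in a
#' background of neutral mutations: everything predating the last selective
#' sweep is clonal with allele frequency exactly 0.5, and the fraction `w`
#' of mutations arising after the sweep follows the neutral 1/f tail on
#' `[f_min, 0.5)`. `f_min` is the minimum measurable allele frequency
#' (avoids the 1/f singularity at zero); `n_snvs` and `read_depth` control
#' simulation size and the Gaussian sequencing-noise variance.
#'
#' @param w neutral fraction in `[0, 1]`.
#' @param f_min minimum measurable AF, in (0, 0.5) (default 0.1).
#' @param n_snvs simulated SNV count (default 300).
#' @param read_depth sequencing depth N for the noise model (default 100).
#' @param t1,t2 optional times (cell cycles) from which `w` can be derived.
#' @param seed optional integer seed.
#' @return List of class `evo_model_params`.
#' @export
evo_model_params <- function(w, f_min = 0.1, n_snvs = 300L,
                             read_depth = 100L, t1 = NULL, t2 = NULL,
                             seed = NULL) {
  stopifnot(w >= 0, w <= 1, f_min > 0, f_min < 0.5, n_snvs >= 1,
            read_depth >= 1)
  structure(list(w = w, f_min = f_min, n_snvs = as.integer(n_snvs),
                 read_depth = as.integer(read_depth), t1 = t1, t2 = t2,
                 seed = seed),
            class = "evo_model_params")
}

#' Neutral fraction from sweep timing under exponential growth
#'
#' With `t1` the time (cell cycles) from the tumor's common ancestor to the
#' last selective sweep and `t2` the time from the sweep to biopsy, an
#' exponentially growing population accumulates `w = 2^t2 / (t1 + 2^t2)` of
#' its mutations after the sweep. Many (t1, t2) pairs share a `w`, which is
#' the model's evolutionary-history degeneracy.
#'
#' @param t1,t2 non-negative times in cell cycles (vectorized).
#' @return Neutral fraction in (0, 1].
#' @export
neutral_fraction_from_times <- function(t1, t2) {
  stopifnot(all(t1 >= 0), all(t2 >= 0))
  2^t2 / (t1 + 2^t2)
}

# nu, phi and the branch half-width of the closed form. phi equals the
# population median AF in the neutral regime.
#' Closed-form intermediates of the evolution model
#'
#' `nu = 2 w f_min / (1 - 2 f_min)`, `phi = nu f_min / (nu - f_min)` and
#' `delta_w = (sqrt(1 + 32 f_min^2) - 1) / (16 f_min)`, the quantities in
#' which the closed-form MATH score is expressed. `phi` is only meaningful
#' for `w` above the clonal regime (`nu > f_min`); the `w = 0` edge where
#' `nu = 0` is guarded (`phi = 0`).
#'
#' @param w neutral fraction.
#' @param f_min minimum measurable AF.
#' @return list with `nu`, `phi`, `delta_w`.
#' @export
closed_form_intermediates <- function(w, f_min = 0.1) {
  nu <- 2 * w * f_min / (1 - 2 * f_min)
  phi <- ifelse(nu == f_min, Inf,
                ifelse(nu == 0, 0, nu * f_min / (nu - f_min)))
  delta_w <- (sqrt(1 + 32 * f_min^2) - 1) / (16 * f_min)
  list(nu = nu, phi = phi, delta_w = delta_w)
}

#' Model allele-frequency CDF
#'
#' Piecewise cumulative distribution of the mutant allele frequency:
#' 0 below `f_min`, `(nu/2) (1/f_min - 1/f)` on `[f_min, 0.5)`, and 1 at
#' `f = 0.5` (the clonal atom carries the remaining mass `1 - w`). The
#' model's support ends at 0.5; evaluating beyond it is an error.
#'
#' @param f allele frequencies in `[0, 0.5]` (vectorized).
#' @param params an [evo_model_params()] (or anything with `w`, `f_min`).
#' @return P(F <= f).
#' @export
af_cdf <- function(f, params) {
  if (any(f < 0 | f > 0.5)) stop("model support is [0, 0.5]")
  nu <- closed_form_intermediates(params$w, params$f_min)$nu
  out <- ifelse(f < params$f_min, 0, (nu / 2) * (1 / params$f_min - 1 / f))
  out[f == 0.5] <- 1
  out
}

#' Sample allele frequencies from the evolution model
#'
#' Inverse-CDF sampling: each draw is clonal (exactly 0.5) with probability
#' `1 - w`, otherwise a neutral-tail value
#' `f = f_min / (1 - u (1 - 2 f_min))` for uniform `u`, which inverts the
#' tail CDF. Deterministic given a seed; the fraction of non-clonal draws
#' converges to `w`.
#'
#' @param params an [evo_model_params()].
#' @param n number of draws (default `params$n_snvs`).
#' @param seed seed (default `params$seed`).
#' @return Numeric vector of AFs in `[f_min, 0.5]`.
#' @export
sample_afs <- function(params, n = params$n_snvs, seed = params$seed) {
  with_seed(seed, {
    neutral <- stats::runif(n) < params$w
    u <- stats::runif(n)
    ifelse(neutral, params$f_min / (1 - u * (1 - 2 * params$f_min)), 0.5)
  })
}

#' Closed-form MATH score of the evolution model
#'
#' The model's MATH score as an explicit function of the neutral fraction:
#' `MATH = 148.26 * B(w, f_min)` where the bracketed term `B` is 0 in the
#' clonal regime (`w <= 1/2`), `1/(2 phi) - 1` for
#' `1/2 < w <= 1/2 + delta_w` (the deviation median sits at the clonal
#' atom), and `(sqrt(nu^2 + phi^2) - nu) / phi` beyond (tail-dominated).
#' The prefactor folds the percentage factor 100 with the scaled-MAD
#' constant 1.4826. Continuous at both branch boundaries; zero throughout
#' the clonal regime; not one-to-one in `w` on the neutral side (it peaks
#' at `w = 1/2 + delta_w` and declines toward `w = 1`), which is why the
#' score cannot distinguish different evolutionary histories.
#'
#' @param w neutral fraction in `[0, 1]` (vectorized).
#' @param f_min minimum measurable AF in (0, 0.5).
#' @param prefactor multiplicative constant (default `100 * 1.4826`).
#' @return MATH score in percent.
#' @export
math_closed_form <- function(w, f_min = 0.1, prefactor = 148.26) {
  stopifnot(all(w >= 0 & w <= 1), f_min > 0, f_min < 0.5)
  ci <- closed_form_intermediates(w, f_min)
  bracket <- ifelse(
    w <= 0.5, 0,
    ifelse(w <= 0.5 + ci$delta_w,
           1 / (2 * ci$phi) - 1,
           (sqrt(ci$nu^2 + ci$phi^2) - ci$nu) / ci$phi))
  prefactor * bracket
}

#' Gaussian sequencing noise on allele frequencies
#'
#' Models the binomial read-sampling error at depth `N` by its Gaussian
#' approximation: each AF `f` is replaced by a draw from
#' `Normal(f, f (1 - f) / N)`. Draws are clipped to `[1e-3, 1 - 1e-3]`
#' (clipping rather than resampling keeps the draw count deterministic).
#' By default the minimum-AF measurement cutoff is not re-applied after
#' noising; set `refilter_f_min` to drop noised values below it.
#'
#' @param afs AF vector in (0, 1).
#' @param read_depth sequencing depth N (default 100).
#' @param seed integer seed.
#' @param refilter_f_min `NULL` (default) or a threshold below which noised
#'   AFs are removed.
#' @return Noised AF vector.
#' @export
add_read_noise <- function(afs, read_depth = 100, seed = NULL,
                           refilter_f_min = NULL) {
  stopifnot(read_depth >= 1, all(afs > 0 & afs < 1))
  noised <- with_seed(seed,
    stats::rnorm(length(afs), mean = afs,
                 sd = sqrt(afs * (1 - afs) / read_depth)))
  noised <- pmin(pmax(noised, 1e-3), 1 - 1e-3)
  if (!is.null(refilter_f_min)) noised <- noised[noised >= refilter_f_min]
  noised
}

#' Evolutionary-history degeneracy surface
#'
#' Evaluates the neutral fraction `w(t1, t2)` and the closed-form MATH
#' score on a grid of sweep timings. All (t1, t2) combinations sharing a
#' `w` value give bitwise-identical MATH scores, demonstrating that the
#' score does not identify the evolutionary history.
#'
#' @param t1_grid,t2_grid non-empty numeric grids (cell cycles).
#' @param f_min minimum measurable AF.
#' @return `data.frame` over the full grid with columns `t1`, `t2`, `w`,
#'   `math`.
#' @export
degeneracy_surface <- function(t1_grid, t2_grid, f_min = 0.1) {
  stopifnot(length(t1_grid) >= 1, length(t2_grid) >= 1)
  g <- expand.grid(t1 = t1_grid, t2 = t2_grid, KEEP.OUT.ATTRS = FALSE)
  g$w <- neutral_fraction_from_times(g$t1, g$t2)
  g$math <- math_closed_form(g$w, f_min)
  g
}
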