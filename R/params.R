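#' Model parameters for the breeding-phenology model
#'
#' Bundles every constant of the model: egg production, incubation, the
#' daily food-gain process, the seasonal clock and the simulated cohort.
#' Defaults describe a large-bodied Arctic sea duck (an eider-like bird)
#' laying one egg per day and incubating a single clutch per season.
#'
#' @param E egg mass (g). Laying one egg withdraws `c * E` grams of
#'   reserves: the egg material plus a prepaid 50% incubation surcharge.
#' @param c reserve-cost multiplier per egg (dimensionless).
#' @param n_max maximal clutch size (eggs).
#' @param I incubation duration (days).
#' @param i_hatch delay from the start of incubation to hatching (days);
#'   identical to `I` in the default parameterization.
#' @param w_a mean net daily food gain while foraging (g/day).
#' @param x1,x2 lower/upper bounds of the daily gain as multiples of `w_a`
#'   (dimensionless); a bird can lose at most `|x1| * w_a` g in a day.
#' @param k number of discrete foraging outcomes.
#' @param alpha shape parameter of the symmetric beta distribution that
#'   weights the foraging outcomes; smaller values mean a more variable
#'   daily gain (the mean is always `w_a`).
#' @param b_s first possible breeding day (day of year): the model's
#'   "spring onset". Laying and incubation are only available from `b_s` on.
#' @param b_ref anchor day of the recruitment decline: the earliest `b_s`
#'   considered across a scenario sweep. Offspring hatched on `b_ref` or
#'   earlier recruit with probability `f_max`.
#' @param T_end last day of the season (day of year); recruitment
#'   probability reaches zero here and no activity is possible afterwards.
#'   The default places the season so that at the earliest spring onset a
#'   deterministic forager can afford a 3-4 egg clutch from pre-breeding
#'   foraging (leaving headroom to `n_max` for lucky foragers), while at
#'   the latest onsets most females approach their reserve ceiling before
#'   breeding opens — the two regimes the strategy comparison contrasts.
#' @param M_L lean body mass (g); reserves come on top of it.
#' @param S_max_capital maximal reserves for a capital breeder (g). The
#'   default `0.3 * M_L` keeps total body mass within 130% of lean mass and
#'   equals `n_max * c * E`, the cost of a full clutch.
#' @param f_max recruitment probability at `b_ref`.
#' @param D_a mean arrival day of the cohort (day of year).
#' @param SD_a standard deviation of the arrival day (days).
#' @param N_pop number of simulated females.
#' @param dS reserve-grid resolution for the dynamic program (g). The
#'   value function is step-like in reserves (an extra egg becomes
#'   affordable at multiples of `c * E`), so the grid must resolve those
#'   kinks for the interpolated backward values to agree with what the
#'   simulated policy actually achieves; 1 g does, at negligible cost.
#' @param seed integer seed for cohort and foraging randomness.
#'
#' @return An object of class `model_params`: a validated named list.
#' @examples
#' p <- model_params()
#' p$c * p$E              # cost of one egg in grams of reserves
#' model_params(b_s = 120, alpha = 0.5)
#' @export
model_params <- function(E = 110, c = 1.5, n_max = 7, I = 26, i_hatch = I,
                         w_a = 15, x1 = -1, x2 = 3, k = 20, alpha = 3,
                         b_s = 100, b_ref = 100, T_end = 200,
                         M_L = 3850, S_max_capital = 0.3 * M_L,
                         f_max = 1, D_a = 90, SD_a = 10, N_pop = 10000,
                         dS = 1, seed = 1L) {
  p <- list(E = E, c = c, n_max = as.integer(n_max), I = as.integer(I),
            i_hatch = as.integer(i_hatch), w_a = w_a, x1 = x1, x2 = x2,
            k = as.integer(k), alpha = alpha, b_s = as.integer(b_s),
            b_ref = as.integer(b_ref), T_end = as.integer(T_end),
            M_L = M_L, S_max_capital = S_max_capital, S_min = 0,
            f_max = f_max, D_a = D_a, SD_a = SD_a,
            N_pop = as.integer(N_pop), dS = dS, seed = as.integer(seed))
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(p$E > 0, p$c > 0, p$n_max >= 1, p$I >= 1, p$i_hatch >= 0,
            p$x1 < p$x2, p$k >= 2, p$alpha > 0, p$dS > 0,
            p$f_max > 0, p$f_max <= 1, p$SD_a >= 0, p$N_pop >= 1)
  cE <- p$c * p$E
  if (!(p$S_min < cE && cE <= p$S_max_capital))
    stop("need S_min < c*E <= S_max_capital: one egg must be affordable")
  if (p$S_max_capital < p$n_max * cE - 1e-9)
    warning("S_max_capital < n_max*c*E: a full clutch is unattainable ",
            "from reserves alone")
  if (!(p$b_ref <= p$b_s && p$b_s < p$T_end - p$I))
    stop("need b_ref <= b_s < T_end - I")
  if ((p$M_L + p$S_max_capital) / p$M_L > 1.30 + 1e-9)
    stop("maximal body mass exceeds 130% of lean mass")
  invisible(p)
}

#' Read model parameters from a YAML or JSON configuration file
#'
#' Every field of [model_params()] may appear by name; missing fields take
#' their defaults. Unknown keys are an error so that typos do not silently
#' fall back to defaults. The season-end day may be written `T_end` (as in
#' the function signature) or `T`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `model_params` object.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)  # YAML superset covers JSON
  if (!is.null(cfg[["T"]])) {
    cfg$T_end <- cfg[["T"]]
    cfg[["T"]] <- NULL
  }
  known <- names(formals(model_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(model_params, cfg)
}
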