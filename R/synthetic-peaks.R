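#' Isotopologue distribution over 15N mass shifts
#'
#' Probability mass over the mass shifts 0..n for a metabolite with `n`
#' nitrogen atoms when each atom is independently 15N with probability
#' `p`. Replacing k atoms shifts the molecular mass by k units (one unit
#' per replaced atom), so entry k+1 of the result is the fraction of the
#' metabolite pool observed at `mass + k` shift units.
#'
#' @param n_nitrogen integer, number of nitrogen atoms (>= 0).
#' @param p probability in \[0, 1\] that any one nitrogen atom is 15N.
#' @return numeric vector of length `n_nitrogen + 1` summing to 1; entry
#'   k+1 is the binomial probability of k replaced atoms.
#' @examples
#' isotopologue_distribution(2, 0.5)  # 0.25 0.50 0.25
#' @export
isotopologue_distribution <- function(n_nitrogen, p) {
  stopifnot(length(n_nitrogen) == 1L, length(p) == 1L)
  if (is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  if (n_nitrogen < 0 || n_nitrogen != round(n_nitrogen)) {
    stop("`n_nitrogen` must be a non-negative integer", call. = FALSE)
  }
  dbinom(0:n_nitrogen, size = n_nitrogen, prob = p)
}

#' Random metabolite panel for peak-list simulation
#'
#' Draws metabolite specifications (monoisotopic mass, nitrogen-atom
#' count, base intensity) with masses rejected until every isotopologue
#' m/z in the panel (mass + 0..n shift units) is separated from every
#' other by more than `min_spacing`, so that features of different
#' metabolites can never fall into the same alignment bin.
#'
#' @param n number of metabolites.
#' @param seed RNG seed.
#' @param mass_range monoisotopic mass range in Da; the instrument records
#'   70-1700 m/z and the assay targets small molecules < 1000 Da.
#' @param n_nitrogen_range inclusive integer range for the per-metabolite
#'   nitrogen-atom count (capped at 10).
#' @param intensity_range range of base intensities (arbitrary units).
#' @param min_spacing minimum separation in Da between any two
#'   isotopologue m/z values of different metabolites.
#' @return data.frame with columns `id`, `monoisotopic_mass`,
#'   `n_nitrogen`, `base_intensity`.
#' @export
random_metabolites <- function(n, seed = 1L,
                               mass_range = c(70, 990),
                               n_nitrogen_range = c(1L, 4L),
                               intensity_range = c(500, 5000),
                               min_spacing = 0.03) {
  stopifnot(n >= 1, mass_range[1] >= 70, mass_range[2] <= 1000,
            n_nitrogen_range[2] <= 10)
  set.seed(seed)
  n_nitrogen <- sample(seq(n_nitrogen_range[1], n_nitrogen_range[2]),
                       n, replace = TRUE)
  max_shift <- max(n_nitrogen)
  masses <- numeric(0)
  occupied <- numeric(0)   # all isotopologue m/z accepted so far
  for (i in seq_len(n)) {
    repeat {
      m <- runif(1, mass_range[1], mass_range[2])
      grid <- m + 0:n_nitrogen[i]
      if (length(occupied) == 0 ||
          min(abs(outer(grid, occupied, "-"))) > min_spacing) {
        masses[i] <- m
        occupied <- c(occupied, grid)
        break
      }
    }
  }
  data.frame(
    id = sprintf("met%03d", seq_len(n)),
    monoisotopic_mass = masses,
    n_nitrogen = n_nitrogen,
    base_intensity = runif(n, intensity_range[1], intensity_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth isolate panel
#'
#' @param n_fixers,n_nonfixers numbers of fixing / non-fixing isolates.
#' @param incorporation per-fixer probability that any one nitrogen atom
#'   is 15N under the enriched atmosphere; recycled/defaulted to an even
#'   grid on \[0.3, 0.9\]. Non-fixers have incorporation 0.
#' @return data.frame with columns `isolate_id`, `incorporation_p`,
#'   `is_fixer`.
#' @export
isolate_truths <- function(n_fixers, n_nonfixers,
                           incorporation = NULL) {
  if (is.null(incorporation)) {
    incorporation <- if (n_fixers > 1) {
      seq(0.3, 0.9, length.out = n_fixers)
    } else {
      rep(0.6, n_fixers)
    }
  }
  stopifnot(length(incorporation) == n_fixers,
            all(incorporation > 0), all(incorporation <= 1))
  n <- n_fixers + n_nonfixers
  data.frame(
    isolate_id = sprintf("iso%03d", seq_len(n)),
    incorporation_p = c(incorporation, rep(0, n_nonfixers)),
    is_fixer = rep(c(TRUE, FALSE), c(n_fixers, n_nonfixers)),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param n_replicates replicate cultures per isolate x atmosphere;
#'   experiments of this kind are typically run in triplicate.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   replicate noise (>= 0).
#' @param detection_floor intensity below which peaks are dropped after
#'   noise, mimicking peak-picking dropout.
#' @param natural_15n background probability that a nitrogen atom is 15N
#'   in the absence of fixation from the enriched atmosphere. Defaults to
#'   natural abundance (0.37%); without any background the control
#'   samples carry zero intensity at shifted masses and the BNF ratio is
#'   undefined. Set to 0 to neglect it.
#' @param mass_shift Da added per replaced nitrogen atom; nominal 1.0 by
#'   default, set to 0.9970 for the exact 15N-14N mass difference.
#' @param seed RNG seed; identical seeds give identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_replicates = 3L, noise_cv = 0.1,
                       detection_floor = 0, natural_15n = 0.0037,
                       mass_shift = 1.0, seed = 1L) {
  if (n_replicates < 2) stop("`n_replicates` must be >= 2", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (natural_15n < 0 || natural_15n > 1) {
    stop("`natural_15n` must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv,
                 detection_floor = detection_floor,
                 natural_15n = natural_15n,
                 mass_shift = mass_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-sample LC-TOF peak lists with known 15N incorporation
#'
#' Emulates cell-extract spectra of isolates cultured under a
#' 15N2-enriched atmosphere and under a control (compressed-air)
#' atmosphere. For each isolate x condition x replicate sample, every
#' metabolite's base intensity is redistributed across its isotopologue
#' masses by [isotopologue_distribution()]: under the enriched condition
#' a fixer incorporates 15N with its own probability, while non-fixers
#' and all control samples sit at the configured background
#' (`natural_15n`). Multiplicative lognormal noise (mean 1, CV
#' `noise_cv`) is applied per peak, then peaks below `detection_floor`
#' are dropped.
#'
#' @param metabolites data.frame as from [random_metabolites()].
#' @param truths data.frame as from [isolate_truths()].
#' @param config a [sim_config()].
#' @return list of class `peak_sim` with elements `peaks` (sample_id, mz,
#'   intensity), `samples` (sample_id, isolate_id, condition in
#'   \{"15N","14N"\}, replicate), `truth` (sample_id, mz, metabolite_id,
#'   shift), and the inputs.
#' @export
simulate_peak_lists <- function(metabolites, truths, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"),
            all(c("id", "monoisotopic_mass", "n_nitrogen",
                  "base_intensity") %in% names(metabolites)),
            all(c("isolate_id", "incorporation_p") %in% names(truths)))
  if (!any(metabolites$n_nitrogen >= 1)) {
    stop("at least one metabolite must contain nitrogen", call. = FALSE)
  }
  if (any(metabolites$monoisotopic_mass < 70 |
          metabolites$monoisotopic_mass > 1000)) {
    stop("metabolite masses must lie in [70, 1000] Da", call. = FALSE)
  }
  if (any(truths$incorporation_p < 0 | truths$incorporation_p > 1)) {
    stop("incorporation probabilities must lie in [0, 1]", call. = FALSE)
  }
  set.seed(config$seed)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  meanlog <- -sdlog^2 / 2   # unit-mean lognormal noise

  samples <- expand.grid(
    replicate = seq_len(config$n_replicates),
    condition = c("15N", "14N"),
    isolate_id = truths$isolate_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("isolate_id", "condition", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$isolate_id,
                               samples$condition, samples$replicate)

  peak_rows <- vector("list", nrow(samples))
  truth_rows <- vector("list", nrow(samples))
  p_lookup <- setNames(truths$incorporation_p, truths$isolate_id)
  for (s in seq_len(nrow(samples))) {
    p_inc <- p_lookup[[samples$isolate_id[s]]]
    p_eff <- if (samples$condition[s] == "15N" && p_inc > 0) {
      p_inc
    } else {
      config$natural_15n
    }
    mzs <- ints <- shifts <- numeric(0)
    ids <- character(0)
    for (m in seq_len(nrow(metabolites))) {
      nn <- metabolites$n_nitrogen[m]
      frac <- isotopologue_distribution(nn, p_eff)
      keep <- frac > 0
      k <- which(keep) - 1L
      mzs <- c(mzs, metabolites$monoisotopic_mass[m] + k * config$mass_shift)
      ints <- c(ints, metabolites$base_intensity[m] * frac[keep])
      shifts <- c(shifts, k)
      ids <- c(ids, rep(metabolites$id[m], length(k)))
    }
    if (config$noise_cv > 0) {
      ints <- ints * rlnorm(length(ints), meanlog, sdlog)
    }
    det <- ints >= config$detection_floor & ints > 0
    peak_rows[[s]] <- data.frame(sample_id = samples$sample_id[s],
                                 mz = mzs[det], intensity = ints[det],
                                 stringsAsFactors = FALSE)
    truth_rows[[s]] <- data.frame(sample_id = samples$sample_id[s],
                                  mz = mzs[det], metabolite_id = ids[det],
                                  shift = shifts[det],
                                  stringsAsFactors = FALSE)
  }
  structure(list(peaks = do.call(rbind, peak_rows),
                 samples = samples[, c("sample_id", "isolate_id",
                                       "condition", "replicate")],
                 truth = do.call(rbind, truth_rows),
                 metabolites = metabolites, truths = truths,
                 config = config),
            class = "peak_sim")
}

#' @export
print.peak_sim <- function(x, ...) {
  cat(sprintf(
    "peak_sim: %d isolates x 2 conditions x %d replicates = %d samples, %d peaks\n",
    nrow(x$truths), x$config$n_replicates, nrow(x$samples), nrow(x$peaks)))
  invisible(x)
}
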