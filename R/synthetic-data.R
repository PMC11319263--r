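#' Trial design for synthetic data generation
#'
#' Describes the scale and noise structure of a synthetic trial: population
#' size, marker panel, linkage disequilibrium, replication and measurement
#' noise. Defaults emulate a greenhouse phenotyping trial of a sorghum
#' diversity panel (four replicates, 45 days, 30/23 degree C day/night) at a
#' desk scale of 300 genotypes by 3,000 markers; the original panel scale
#' (136 genotypes, 31,713 markers) is reachable through the arguments.
#'
#' @param n_genotypes Number of genotypes (>= 2).
#' @param n_markers Number of biallelic markers (>= 1).
#' @param n_chromosomes Chromosome count; markers are split into
#'   `ceiling(p / n_chromosomes)` consecutive blocks (last truncated).
#' @param ld_rho First-order Markov haplotype-copying probability in
#'   `[0, 1)`: the strength of adjacent-marker linkage disequilibrium.
#' @param maf_min Minimum minor allele frequency enforced on the emitted
#'   matrix, in `[0, 0.5)`.
#' @param replicates Replicate plants per genotype (>= 1).
#' @param duration_days Trial length in days.
#' @param noise_cv Multiplicative lognormal measurement noise CV, either a
#'   single value for all traits or a named vector per trait.
#' @param day_temp,night_temp Greenhouse set point temperatures (degrees C).
#' @param radiation_mean Mean daily incident radiation (MJ m^-2 day^-1).
#' @param radiation_cv Lognormal CV of daily radiation.
#' @param temp_jitter_sd Gaussian jitter SD on the daily mean temperature.
#' @return List of class `trial_design`.
#' @export
trial_design <- function(n_genotypes = 300, n_markers = 3000,
                         n_chromosomes = 10, ld_rho = 0.9, maf_min = 0.05,
                         replicates = 4, duration_days = 45, noise_cv = 0.1,
                         day_temp = 30, night_temp = 23, radiation_mean = 8,
                         radiation_cv = 0.2, temp_jitter_sd = 0.3) {
  stopifnot(n_genotypes >= 2, n_markers >= 1, n_chromosomes >= 1,
            ld_rho >= 0, ld_rho < 1, replicates >= 1, duration_days >= 1)
  if (maf_min < 0 || maf_min >= 0.5) stop("unattainable MAF")
  d <- list(n_genotypes = as.integer(n_genotypes),
            n_markers = as.integer(n_markers),
            n_chromosomes = as.integer(n_chromosomes), ld_rho = ld_rho,
            maf_min = maf_min, replicates = as.integer(replicates),
            duration_days = as.integer(duration_days), noise_cv = noise_cv,
            day_temp = day_temp, night_temp = night_temp,
            radiation_mean = radiation_mean, radiation_cv = radiation_cv,
            temp_jitter_sd = temp_jitter_sd)
  class(d) <- "trial_design"
  d
}

#' Simulate a marker matrix with linkage disequilibrium
#'
#' Each genotype carries two haplotypes per chromosome. Along a chromosome
#' the allele at a marker is copied from the previous marker with
#' probability `ld_rho`, otherwise redrawn from that marker's allele
#' frequency (first-order Markov copying). Genotypes are coded
#' `{-1, 0, 1}` (reference homozygote, heterozygote, alternative
#' homozygote). Markers whose empirical minor allele frequency falls below
#' `maf_min` are repaired by flipping the minimum number of haplotype
#' alleles at random rows, so the emitted matrix always satisfies the MAF
#' floor.
#'
#' @param design A [trial_design()].
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return Integer matrix `n_genotypes x n_markers` with `dimnames`
#'   (genotype ids `G001...`, marker ids `chr<c>_m<j>`).
#' @export
simulate_genotypes <- function(design, seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  n <- design$n_genotypes; p <- design$n_markers
  set.seed(seed)
  per_chr <- ceiling(p / design$n_chromosomes)
  chr <- rep(seq_len(design$n_chromosomes), each = per_chr)[seq_len(p)]
  # allele frequencies kept away from the boundary so the empirical MAF
  # floor is rarely violated at the sampled size
  f_lo <- max(design$maf_min + 0.02, 0.1)
  freq <- runif(p, f_lo, 1 - f_lo)
  H <- matrix(0L, 2L * n, p)
  for (j in seq_len(p)) {
    draw <- as.integer(runif(2L * n) < freq[j])
    if (j > 1L && chr[j] == chr[j - 1L]) {
      copy <- runif(2L * n) < design$ld_rho
      H[, j] <- ifelse(copy, H[, j - 1L], draw)
    } else {
      H[, j] <- draw
    }
  }
  # enforce the MAF floor exactly: flip major -> minor alleles as needed
  need <- ceiling(design$maf_min * 2 * n)
  cnt <- colSums(H)
  for (j in which(pmin(cnt, 2L * n - cnt) < need)) {
    minor_is_1 <- cnt[j] <= n  # allele coded 1 is the minor one
    k <- need - min(cnt[j], 2L * n - cnt[j])
    major_rows <- which(H[, j] == as.integer(!minor_is_1))
    flip <- sample(major_rows, k)
    H[flip, j] <- as.integer(minor_is_1)
  }
  X <- H[seq(1, 2L * n, by = 2), , drop = FALSE] +
    H[seq(2, 2L * n, by = 2), , drop = FALSE] - 1L
  dimnames(X) <- list(sprintf("G%03d", seq_len(n)),
                      sprintf("chr%d_m%d", chr, seq_len(p)))
  X
}

#' Genetic architecture linking markers to growth model parameters
#'
#' For every genotypic parameter, a list of additive QTL (marker index and
#' effect), an optional list of epistatic marker pairs whose interaction
#' acts through the product of the `{-1,0,1}` codes, and a target
#' narrow-sense heritability.
#'
#' @param qtl Named list (one element per parameter) of data frames with
#'   columns `marker` (1-based index) and `effect`.
#' @param epistasis Named list of data frames with columns `marker_i`,
#'   `marker_j`, `effect` (may be empty).
#' @param h2 Named numeric vector of target heritabilities in `[0, 1]`.
#' @param bounds Parameter bounds matrix, see [parameter_bounds()].
#' @return List of class `genetic_architecture`.
#' @export
genetic_architecture <- function(qtl, epistasis = NULL, h2,
                                 bounds = parameter_bounds()) {
  nm <- colnames(bounds)
  stopifnot(all(nm %in% names(qtl)), all(nm %in% names(h2)))
  if (is.null(epistasis))
    epistasis <- stats::setNames(replicate(length(nm), NULL), nm)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  a <- list(qtl = qtl[nm], epistasis = epistasis[nm], h2 = h2[nm],
            bounds = bounds)
  class(a) <- "genetic_architecture"
  a
}

#' Draw a random genetic architecture
#'
#' Additive effects are standard normal at `n_qtl` markers sampled uniformly
#' along the panel; epistatic pairs (if requested) are adjacent-marker pairs
#' — interactions between tightly linked loci, the kind a convolutional
#' network with a local receptive field can in principle detect — with
#' standard normal interaction effects.
#'
#' @param p Number of markers in the panel.
#' @param n_qtl Additive QTL per parameter.
#' @param n_pairs Epistatic pairs per parameter.
#' @param h2_range Target heritability range; one value per parameter is
#'   drawn uniformly within it.
#' @param bounds Parameter bounds matrix.
#' @param seed Integer seed.
#' @return A [genetic_architecture()].
#' @export
random_architecture <- function(p, n_qtl = 30, n_pairs = 0,
                                h2_range = c(0.5, 0.9),
                                bounds = parameter_bounds(), seed = 1) {
  set.seed(seed)
  nm <- colnames(bounds)
  qtl <- epi <- stats::setNames(vector("list", length(nm)), nm)
  for (k in nm) {
    qtl[[k]] <- data.frame(marker = sample.int(p, n_qtl),
                           effect = stats::rnorm(n_qtl))
    if (n_pairs > 0) {
      i <- sample.int(p - 1L, n_pairs)
      epi[[k]] <- data.frame(marker_i = i, marker_j = i + 1L,
                             effect = stats::rnorm(n_pairs))
    }
  }
  h2 <- stats::setNames(stats::runif(length(nm), h2_range[1], h2_range[2]), nm)
  genetic_architecture(qtl, epi, h2, bounds)
}

#' Simulate "true" genotypic parameters from markers
#'
#' For each parameter, the genetic score of genotype i is
#' `sum(additive effects * code) + sum(interaction effects * code_i *
#' code_j)`. The score is standardized, Gaussian environmental (and
#' developmental) noise is added so that `var(g) / var(g + e)` equals the
#' target heritability, and the result is mapped affinely onto the
#' parameter's calibration interval by population min-max. The affine map
#' preserves the heritability of the underlying liability.
#'
#' @param markers Marker matrix from [simulate_genotypes()].
#' @param arch A [genetic_architecture()].
#' @param seed Integer seed.
#' @return Numeric matrix `n x 8` of parameter values (rows named by
#'   genotype), every entry inside its interval.
#' @export
simulate_parameters <- function(markers, arch, seed = 1) {
  stopifnot(inherits(arch, "genetic_architecture"))
  set.seed(seed)
  n <- nrow(markers); p <- ncol(markers)
  nm <- colnames(arch$bounds)
  out <- matrix(NA_real_, n, length(nm),
                dimnames = list(rownames(markers), nm))
  for (k in nm) {
    q <- arch$qtl[[k]]; e <- arch$epistasis[[k]]; h2 <- arch$h2[[k]]
    g <- numeric(n)
    n_terms <- 0L
    if (!is.null(q) && nrow(q)) {
      if (any(q$marker < 1 | q$marker > p)) stop("QTL index out of range")
      g <- g + as.numeric(markers[, q$marker, drop = FALSE] %*% q$effect)
      n_terms <- n_terms + nrow(q)
    }
    if (!is.null(e) && nrow(e)) {
      if (any(c(e$marker_i, e$marker_j) < 1 | c(e$marker_i, e$marker_j) > p))
        stop("epistatic index out of range")
      prod_codes <- markers[, e$marker_i, drop = FALSE] *
        markers[, e$marker_j, drop = FALSE]
      g <- g + as.numeric(prod_codes %*% e$effect)
      n_terms <- n_terms + nrow(e)
    }
    if (h2 > 0 && n_terms == 0L)
      stop("empty QTL list with positive target heritability for ", k)
    vg <- stats::var(g)
    if (h2 > 0 && vg == 0)
      stop("zero genetic variance with positive target heritability for ", k)
    if (vg > 0) g <- (g - mean(g)) / sqrt(vg)
    y <- if (h2 >= 1) g
    else if (h2 <= 0) stats::rnorm(n)
    else g + stats::rnorm(n, sd = sqrt((1 - h2) / h2))
    lo <- arch$bounds["lower", k]; hi <- arch$bounds["upper", k]
    rng <- range(y)
    out[, k] <- if (diff(rng) == 0) rep((lo + hi) / 2, n)
    else lo + (hi - lo) * (y - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Simulate a daily weather series
#'
#' Daily mean temperature is the 12 h day / 12 h night average of the two
#' greenhouse set points plus Gaussian jitter; radiation is lognormal around
#' its mean with the given CV.
#'
#' @param days Series length (>= 1).
#' @param day_temp,night_temp Set point temperatures (degrees C).
#' @param radiation_mean Mean daily radiation (MJ m^-2 day^-1, > 0).
#' @param radiation_cv Lognormal coefficient of variation (0 gives a
#'   constant series).
#' @param temp_jitter_sd SD of the temperature jitter (0 gives constant
#'   temperature).
#' @param seed Integer seed.
#' @return Data frame with columns `day`, `tmean_C`, `rad_MJ_m2`.
#' @export
simulate_weather <- function(days = 45, day_temp = 30, night_temp = 23,
                             radiation_mean = 8, radiation_cv = 0.2,
                             temp_jitter_sd = 0.3, seed = 1) {
  stopifnot(days >= 1)
  if (radiation_mean <= 0) stop("radiation_mean must be positive")
  set.seed(seed)
  tmean <- (day_temp * 12 + night_temp * 12) / 24 +
    (if (temp_jitter_sd > 0) stats::rnorm(days, 0, temp_jitter_sd) else 0)
  rad <- if (radiation_cv > 0) {
    sdlog <- sqrt(log(1 + radiation_cv^2))
    stats::rlnorm(days, log(radiation_mean) - sdlog^2 / 2, sdlog)
  } else rep(radiation_mean, days)
  data.frame(day = seq_len(days), tmean_C = tmean, rad_MJ_m2 = rad)
}

#' Traits used for growth model calibration
#'
#' The seven measured traits entering the Differential Evolution objective:
#' weekly counts (appeared and ligulated mainstem leaves, tillers), daily
#' fresh biomass and plant height, and two harvest traits.
#'
#' @return Character vector of length 7.
#' @export
calibration_traits <- function() {
  c("App", "Lig", "Tillernb", "Biomaerofw", "PHT", "Mainstemfw", "Arealfel")
}

#' Simulate a replicated, noisy phenotyping trial
#'
#' Runs the growth model once per genotype under the shared weather series,
#' then emits per-replicate measurements with multiplicative lognormal noise
#' at each trait's CV, at the platform's cadence: daily for `Biomaerofw`,
#' `PLA` and `PHT`, weekly for `App`, `Lig` and `Tillernb`, and at harvest
#' (final day) for `Mainstemfw` and `Arealfel`.
#'
#' @param true_params Matrix of genotypic parameters (one row per genotype),
#'   as from [simulate_parameters()].
#' @param weather Weather data frame covering the trial duration.
#' @param design A [trial_design()] (replicates, duration, noise CVs).
#' @param constants [model_constants()] list.
#' @param seed Integer seed for the measurement noise.
#' @return List with `phenotypes` (tidy data frame: `genotype_id`,
#'   `replicate`, `day`, `trait`, `value`) and `simulations` (named list of
#'   the noiseless `cgm_simulation` objects).
#' @export
simulate_trial <- function(true_params, weather, design,
                           constants = model_constants(), seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  weather <- validate_weather(weather)
  if (nrow(weather) < design$duration_days)
    stop("weather series shorter than the trial duration")
  weather <- weather[seq_len(design$duration_days), ]
  set.seed(seed)
  ids <- rownames(true_params)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(nrow(true_params)))
  dur <- design$duration_days
  daily_tr <- c("Biomaerofw", "PLA", "PHT")
  weekly_tr <- c("App", "Lig", "Tillernb")
  weekly_days <- seq(7, dur, by = 7)
  cvs <- trait_cvs(design$noise_cv)
  sims <- vector("list", length(ids)); names(sims) <- ids
  pieces <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sim <- simulate_growth(true_params[i, ], weather, constants)
    sims[[i]] <- sim
    base <- rbind(
      expand_trait(sim, daily_tr, seq_len(dur)),
      expand_trait(sim, weekly_tr, weekly_days),
      data.frame(day = dur, trait = c("Mainstemfw", "Arealfel"),
                 value = c(sim$harvest$Mainstemfw, sim$harvest$Arealfel)))
    reps <- lapply(seq_len(design$replicates), function(r) {
      cv <- cvs[base$trait]
      sdlog <- sqrt(log(1 + cv^2))
      noise <- exp(stats::rnorm(nrow(base), -sdlog^2 / 2, sdlog))
      data.frame(genotype_id = ids[i], replicate = r, day = base$day,
                 trait = base$trait, value = base$value * noise)
    })
    pieces[[i]] <- do.call(rbind, reps)
  }
  list(phenotypes = do.call(rbind, pieces), simulations = sims)
}

trait_cvs <- function(noise_cv) {
  traits <- c("Biomaerofw", "PLA", "PHT", "App", "Lig", "Tillernb",
              "Mainstemfw", "Arealfel")
  if (length(noise_cv) == 1L && is.null(names(noise_cv)))
    return(stats::setNames(rep(noise_cv, length(traits)), traits))
  cv <- stats::setNames(rep(0.1, length(traits)), traits)
  cv[names(noise_cv)] <- noise_cv
  cv
}

expand_trait <- function(sim, traits, days) {
  do.call(rbind, lapply(traits, function(tr)
    data.frame(day = days, trait = tr,
               value = simulated_trait(sim, tr, days))))
}

#' Observed integrative trait from a synthetic trial
#'
#' The per-genotype replicate mean of the noisy final-day aboveground fresh
#' weight — the synthetic analogue of the genotype-level value entering the
#' direct genomic prediction scenario.
#'
#' @param phenotypes Tidy phenotype table from [simulate_trial()].
#' @return Named numeric vector (one value per genotype).
#' @export
observed_biomass <- function(phenotypes) {
  final_day <- max(phenotypes$day)
  sub <- phenotypes[phenotypes$trait == "Biomaerofw" &
                      phenotypes$day == final_day, ]
  tapply(sub$value, sub$genotype_id, mean)[unique(phenotypes$genotype_id)]
}
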