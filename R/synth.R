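#' Synthetic-cohort configuration
#'
#' Bundles and validates the parameters of the synthetic longitudinal cohort
#' generator. Defaults reproduce the scale of a three-visit middle-aged
#' Chinese cohort profiled for 413 serum proteins: 3415 participants split
#' into discovery and validation batches at a 1785:1630 ratio, 72% female,
#' baseline age 57.5 (SD 5.1) years, visits 3.3 years apart.
#'
#' @param n_participants number of participants.
#' @param n_proteins number of protein columns.
#' @param n_visits number of visits (>= 2).
#' @param visit_spacing_years years between consecutive visits.
#' @param frac_female proportion of female participants.
#' @param age_mean,age_sd baseline chronological age distribution (years).
#' @param n_bmd_proteins number of proteins causally tied to BMD.
#' @param bmd_effect_sd_per_sd absolute effect of each causal protein on
#'   BMD, in population-SD of BMD per SD of protein (signs are random).
#' @param n_age_proteins number of proteins linearly coupled to biological
#'   age.
#' @param age_protein_r target absolute correlation between each age-coupled
#'   protein and chronological age.
#' @param accel_sd SD of the true biological-age acceleration Delta (years).
#' @param accel_slope_coupling additional BMD slope per SD of Delta
#'   (BMD-SD per year; negative = accelerated bone loss).
#' @param missing_rate fraction of each protein's lowest values removed as
#'   left-censored (below detection limit).
#' @param batch_shift_sd SD of a per-protein additive batch effect applied
#'   to the validation batch, in units of the protein's own SD.
#' @param confound_sd loading of (BMI, age) confounders on non-causal
#'   proteins, in protein-SD units.
#' @param batch_frac fraction of participants assigned to the discovery
#'   batch.
#' @param tscore_ref_mean,tscore_ref_sd young-adult reference BMD mean and
#'   SD (g/cm^2) per site, named `ls` and `fn`.
#' @param seed integer seed driving all randomness.
#' @return a validated list of class `SynthConfig`.
#' @export
synthConfig <- function(n_participants = 3415L,
                        n_proteins = 413L,
                        n_visits = 3L,
                        visit_spacing_years = 3.3,
                        frac_female = 0.72,
                        age_mean = 57.5,
                        age_sd = 5.1,
                        n_bmd_proteins = 8L,
                        bmd_effect_sd_per_sd = 0.3,
                        n_age_proteins = 12L,
                        age_protein_r = 0.3,
                        accel_sd = 5,
                        accel_slope_coupling = -0.05,
                        missing_rate = 0.10,
                        batch_shift_sd = 0,
                        confound_sd = 0.1,
                        batch_frac = 1785 / 3415,
                        tscore_ref_mean = c(ls = 1.047, fn = 0.858),
                        tscore_ref_sd = c(ls = 0.110, fn = 0.120),
                        seed = 1L) {
    cfg <- list(n_participants = as.integer(n_participants),
                n_proteins = as.integer(n_proteins),
                n_visits = as.integer(n_visits),
                visit_spacing_years = visit_spacing_years,
                frac_female = frac_female,
                age_mean = age_mean, age_sd = age_sd,
                n_bmd_proteins = as.integer(n_bmd_proteins),
                bmd_effect_sd_per_sd = bmd_effect_sd_per_sd,
                n_age_proteins = as.integer(n_age_proteins),
                age_protein_r = age_protein_r,
                accel_sd = accel_sd,
                accel_slope_coupling = accel_slope_coupling,
                missing_rate = missing_rate,
                batch_shift_sd = batch_shift_sd,
                confound_sd = confound_sd,
                batch_frac = batch_frac,
                tscore_ref_mean = tscore_ref_mean,
                tscore_ref_sd = tscore_ref_sd,
                seed = as.integer(seed))
    class(cfg) <- "SynthConfig"
    validateSynthConfig(cfg)
    cfg
}

#' @rdname synthConfig
#' @param config a `SynthConfig`.
#' @export
validateSynthConfig <- function(config) {
    stopifnot(inherits(config, "SynthConfig"))
    if (config$n_participants < 10L)
        stop("invalid config: n_participants must be >= 10")
    if (config$n_visits < 2L)
        stop("invalid config: n_visits must be >= 2")
    if (config$n_bmd_proteins + config$n_age_proteins > config$n_proteins)
        stop("invalid config: n_bmd_proteins + n_age_proteins exceeds ",
             "n_proteins (overlapping causal sets are not supported)")
    props <- c(frac_female = config$frac_female,
               missing_rate = config$missing_rate,
               batch_frac = config$batch_frac)
    if (any(props < 0 | props > 1))
        stop("invalid config: proportions must lie in [0, 1]: ",
             paste(names(props)[props < 0 | props > 1], collapse = ", "))
    if (config$age_sd <= 0 || config$accel_sd < 0 ||
        config$batch_shift_sd < 0 || config$visit_spacing_years <= 0)
        stop("invalid config: scale parameters must be positive")
    if (config$age_protein_r <= 0 || config$age_protein_r >= 1)
        stop("invalid config: age_protein_r must lie in (0, 1)")
    invisible(config)
}

# Fixed structural constants of the BMD generating model (population-SD
# scale). Chosen once for realism: cross-sectional age gradient, male-female
# BMD offset, weak BMI/activity confounding, annual decline near 1%/year for
# women, and measurement noise typical of DXA repositioning error.
.bmd_gen <- list(beta_age = -0.25, beta_sex_male = 0.35,
                 beta_bmi = 0.15, beta_pa = 0.05,
                 intercept_sd = 0.35, noise_sd = 0.20,
                 slope_female = -0.05, slope_male = -0.02,
                 slope_sd = 0.015,
                 t_mean = c(ls = -1.05, fn = -0.85),
                 visit_noise_ratio = 0.3)

#' Generate a synthetic longitudinal proteomic cohort
#'
#' Simulates a person-visit cohort with a latent bone-aging process:
#' a subset of proteins causally shifts BMD level (random signs, fixed
#' magnitude), a person-specific random slope plus an age-acceleration term
#' Delta drives BMD decline, a disjoint protein subset tracks true
#' biological age (chronological age + Delta), protein values below each
#' protein's detection quantile are left-censored to `NA`, and participants
#' are split into discovery/validation batches. Osteoporosis status is not
#' simulated directly: it derives downstream from T-scores of the simulated
#' BMD, keeping the ground truth coherent across analysis stages.
#'
#' @param config a [synthConfig()] object.
#' @return a [ProteoCohort-class]; `groundTruth(x)` holds the causal protein
#'   identities and betas, the age-protein calibration (q, k, s), the true
#'   acceleration Delta, true biological age, per-participant BMD slopes and
#'   the true (risk-oriented) protein score.
#' @examples
#' coh <- simulateCohort(synthConfig(n_participants = 50, n_proteins = 30,
#'                                   seed = 7))
#' dim(proteinMatrix(coh))
#' @export
simulateCohort <- function(config = synthConfig()) {
    validateSynthConfig(config)
    set.seed(config$seed)
    n <- config$n_participants
    p <- config$n_proteins
    V <- config$n_visits
    g <- .bmd_gen

    pid <- sprintf("S%05d", seq_len(n))
    prot <- sprintf("P%03d", seq_len(p))
    tvis <- (seq_len(V) - 1L) * config$visit_spacing_years

    sex <- ifelse(runif(n) < config$frac_female, "female", "male")
    male <- as.numeric(sex == "male")
    age0 <- rnorm(n, config$age_mean, config$age_sd)
    delta <- rnorm(n, 0, config$accel_sd)
    delta <- delta - mean(delta)       # ground-truth acceleration centred
    std_age <- (age0 - config$age_mean) / config$age_sd

    covars <- .simulateCovariates(n, male, std_age)
    std_bmi <- (covars$bmi - 23.3) / 3.0

    batch <- rep("validation", n)
    batch[sample.int(n, round(n * config$batch_frac))] <- "discovery"

    bmd_idx <- seq_len(config$n_bmd_proteins)
    age_idx <- config$n_bmd_proteins + seq_len(config$n_age_proteins)
    noise_idx <- setdiff(seq_len(p), c(bmd_idx, age_idx))

    # abundance scale chosen so that the half-minimum substitute for
    # left-censored values lands just below the censoring window rather
    # than as an extreme outlier
    mu_j <- runif(p, 4, 7)
    sd_j <- runif(p, 0.8, 1.2)

    # non-age proteins: person-stable trait + visit-level noise, unit SD
    nu <- g$visit_noise_ratio
    zeta <- matrix(rnorm(n * p), n, p)             # person traits
    abun <- array(NA_real_, c(n, V, p))
    for (v in seq_len(V)) {
        gv <- (zeta + nu * matrix(rnorm(n * p), n, p)) / sqrt(1 + nu^2)
        abun[, v, ] <- gv
    }
    if (length(noise_idx) && config$confound_sd > 0) {
        conf <- config$confound_sd * (0.6 * std_bmi + 0.4 * std_age)
        for (v in seq_len(V))
            abun[, v, noise_idx] <- abun[, v, noise_idx] + conf
    }
    for (v in seq_len(V))
        abun[, v, ] <- sweep(sweep(abun[, v, ], 2, sd_j, `*`), 2, mu_j, `+`)

    # the causal exposure is the sample-standardized baseline abundance
    z_causal <- matrix(0, n, length(bmd_idx))
    if (length(bmd_idx))
        z_causal <- scale(matrix(abun[, 1L, bmd_idx], n, length(bmd_idx)))

    # age-coupled proteins overwrite their columns: x = q + k*BA + e
    k_j <- sample(c(-1, 1), length(age_idx), TRUE) *
        runif(length(age_idx), 0.06, 0.12)
    q_j <- runif(length(age_idx), 4, 7) - k_j * config$age_mean
    s_j <- abs(k_j) * config$age_sd *
        sqrt(1 / config$age_protein_r^2 - 1)
    for (v in seq_len(V)) {
        ba_v <- age0 + tvis[v] + delta
        abun[, v, age_idx] <- outer(ba_v, k_j) +
            matrix(q_j, n, length(age_idx), byrow = TRUE) +
            matrix(rnorm(n * length(age_idx)), n) *
                matrix(s_j, n, length(age_idx), byrow = TRUE)
    }

    # BMD on the population-SD scale, then mapped to g/cm^2 via T-scores
    beta_sign <- sample(c(-1, 1), length(bmd_idx), TRUE)
    beta_bmd <- beta_sign * config$bmd_effect_sd_per_sd
    prot_part <- as.vector(z_causal %*% beta_bmd)
    lin <- g$beta_age * std_age + g$beta_sex_male * male +
        g$beta_bmi * std_bmi +
        g$beta_pa * (covars$physical_activity - 41.4) / 17.4 + prot_part

    slope_mean <- ifelse(male == 1, g$slope_male, g$slope_female)
    accel_term <- if (config$accel_sd > 0)
        config$accel_slope_coupling * delta / config$accel_sd else 0
    bmd <- list()
    truth_slopes <- list()
    for (site in c("ls", "fn")) {
        u <- rnorm(n, 0, g$intercept_sd)
        slope <- slope_mean + rnorm(n, 0, g$slope_sd) + accel_term
        B <- outer(lin + u, rep(1, V)) + outer(slope, tvis) +
            matrix(rnorm(n * V, 0, g$noise_sd), n, V)
        Tsc <- g$t_mean[[site]] + B
        bmd[[site]] <- config$tscore_ref_mean[[site]] +
            config$tscore_ref_sd[[site]] * Tsc
        truth_slopes[[site]] <- slope
    }

    # long format: participant-major, visit-minor
    idx_p <- rep(seq_len(n), each = V)
    idx_v <- rep(seq_len(V), times = n)
    coldata <- data.frame(
        participant = pid[idx_p],
        visit = idx_v,
        time_years = tvis[idx_v],
        age = age0[idx_p] + tvis[idx_v],
        sex = sex[idx_p],
        batch = batch[idx_p],
        bmd_ls = t(bmd$ls)[cbind(idx_v, idx_p)],
        bmd_fn = t(bmd$fn)[cbind(idx_v, idx_p)],
        covars[idx_p, , drop = FALSE],
        row.names = paste0(pid[idx_p], "_V", idx_v),
        stringsAsFactors = FALSE)

    amat <- matrix(NA_real_, n * V, p, dimnames =
                       list(rownames(coldata), prot))
    for (v in seq_len(V))
        amat[idx_v == v, ] <- abun[, v, ]

    # left-censoring: drop exactly the lowest missing_rate fraction per
    # protein (rank-based, so the removed count is exact up to rounding)
    if (config$missing_rate > 0) {
        n_miss <- round(config$missing_rate * nrow(amat))
        if (n_miss > 0)
            for (j in seq_len(p)) {
                cutidx <- order(amat[, j])[seq_len(n_miss)]
                amat[cutidx, j] <- NA_real_
            }
    }

    if (config$batch_shift_sd > 0) {
        eta <- rnorm(p, 0, config$batch_shift_sd) * sd_j
        vrows <- coldata$batch == "validation"
        amat[vrows, ] <- sweep(amat[vrows, , drop = FALSE], 2, eta, `+`)
    }

    truth <- list(
        bmd_proteins = data.frame(protein = prot[bmd_idx],
                                  beta_ls = beta_bmd, beta_fn = beta_bmd,
                                  stringsAsFactors = FALSE),
        age_proteins = data.frame(protein = prot[age_idx],
                                  q = q_j, k = k_j, s = s_j,
                                  stringsAsFactors = FALSE),
        delta = setNames(delta, pid),
        ba_true = setNames(age0 + delta, pid),
        bmd_slope = data.frame(participant = pid,
                               slope_ls = truth_slopes$ls,
                               slope_fn = truth_slopes$fn,
                               stringsAsFactors = FALSE),
        prs_true = setNames(as.vector(z_causal %*% (-beta_bmd)), pid),
        config = config)

    ProteoCohort(abundance = t(amat), colData = coldata,
                 metadata = list(ground_truth = truth,
                                 tscore_ref_mean = config$tscore_ref_mean,
                                 tscore_ref_sd = config$tscore_ref_sd))
}

.simulateCovariates <- function(n, male, std_age) {
    tc <- rnorm(n, 5.42, 1.07)
    data.frame(
        bmi = rnorm(n, 23.3, 3.0),
        whr = rnorm(n, 0.88, 0.08) + 0.03 * male,
        physical_activity = pmax(0, rnorm(n, 41.4, 17.4)),
        sbp = 124 + 4 * std_age + rnorm(n, 0, 16),
        dbp = rnorm(n, 78.3, 10.7),
        glucose = pmax(2.5, rnorm(n, 4.77, 1.0)),
        tc = tc,
        tg = pmax(0.2, rnorm(n, 1.58, 1.0)),
        ldl = 3.62 + 0.5 * (tc - 5.42) * 0.91 / 1.07 +
            rnorm(n, 0, 0.91 * sqrt(0.75)),
        hdl = pmax(0.4, rnorm(n, 1.37, 0.35)),
        uric_acid = pmax(80, 279 + 40 * male + rnorm(n, 0, 100)),
        energy = pmax(500, rnorm(n, 1856, 617)),
        carbohydrate = pmax(50, rnorm(n, 223, 41)),
        fiber = pmax(1, rnorm(n, 10.7, 5.1)),
        smoking = as.integer(runif(n) < ifelse(male == 1, 0.45, 0.03)),
        alcohol = as.integer(runif(n) < 0.06),
        tea = as.integer(runif(n) < 0.5),
        calcium_supp = as.integer(runif(n) < 0.32),
        multivit = as.integer(runif(n) < 0.22),
        stringsAsFactors = FALSE)
}

#' Generate two-sample MR summary statistics with known causal effect
#'
#' Per SNP i, the exposure effect is gamma_i (drawn uniformly with random
#' sign) observed as `beta_x ~ N(gamma_i, se_x^2)`; the outcome effect is
#' `beta_y ~ N(theta_true * gamma_i + alpha_i, se_y^2)` where `alpha_i` is a
#' horizontal-pleiotropy intercept drawn as
#' `N(pleiotropy_mean, pleiotropy_sd^2)` for a fraction `frac_pleiotropic`
#' of SNPs (0 for the rest). Exposure/outcome effects refer to the same
#' effect allele, i.e. the set is already harmonized.
#'
#' @param n_snps number of instruments (>= 1).
#' @param theta_true true causal effect of exposure on outcome.
#' @param pleiotropy_sd SD of per-SNP pleiotropic effects (>= 0).
#' @param seed integer seed.
#' @param frac_pleiotropic fraction of SNPs carrying pleiotropy.
#' @param pleiotropy_mean mean pleiotropic effect (nonzero = directional).
#' @param se_x_range,se_y_range uniform ranges for the standard errors.
#' @param pleiotropic_gamma_range optional uniform range for the exposure
#'   effects of pleiotropic SNPs; a lower range makes invalid instruments
#'   weaker, keeping the majority of inverse-variance weight on valid
#'   ones (the regime in which median-based estimators are consistent).
#' @param positive_gamma orient all instruments to positive exposure
#'   effects (the convention under which directional pleiotropy biases
#'   IVW in one direction).
#' @return list with `instruments` (data.frame: snp, effect_allele,
#'   other_allele, eaf, beta_x, se_x, p_x, beta_y, se_y) and `truth`
#'   (theta, per-SNP gamma and alpha).
#' @export
simulateMrSummary <- function(n_snps, theta_true, pleiotropy_sd, seed = 1L,
                              frac_pleiotropic = 1, pleiotropy_mean = 0,
                              se_x_range = c(0.008, 0.012),
                              se_y_range = c(0.008, 0.015),
                              pleiotropic_gamma_range = NULL,
                              positive_gamma = FALSE) {
    if (n_snps < 1L) stop("n_snps must be >= 1")
    if (pleiotropy_sd < 0) stop("pleiotropy_sd must be >= 0")
    set.seed(seed)
    gamma <- sample(c(-1, 1), n_snps, TRUE) * runif(n_snps, 0.08, 0.2)
    if (positive_gamma) gamma <- abs(gamma)
    se_x <- runif(n_snps, se_x_range[1], se_x_range[2])
    se_y <- runif(n_snps, se_y_range[1], se_y_range[2])
    alpha <- numeric(n_snps)
    which_pleio <- runif(n_snps) < frac_pleiotropic
    alpha[which_pleio] <- rnorm(sum(which_pleio), pleiotropy_mean,
                                pleiotropy_sd)
    if (!is.null(pleiotropic_gamma_range) && any(which_pleio))
        gamma[which_pleio] <- sign(gamma[which_pleio]) *
            runif(sum(which_pleio), pleiotropic_gamma_range[1],
                  pleiotropic_gamma_range[2])
    beta_x <- rnorm(n_snps, gamma, se_x)
    beta_y <- rnorm(n_snps, theta_true * gamma + alpha, se_y)
    alleles <- t(vapply(seq_len(n_snps), function(i)
        sample(c("A", "C", "G", "T"), 2), character(2)))
    instruments <- data.frame(
        snp = sprintf("rs%06d", seq_len(n_snps)),
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        eaf = runif(n_snps, 0.1, 0.9),
        beta_x = beta_x, se_x = se_x,
        p_x = 2 * pnorm(-abs(beta_x / se_x)),
        beta_y = beta_y, se_y = se_y,
        stringsAsFactors = FALSE)
    list(instruments = instruments,
         truth = list(theta = theta_true, gamma = gamma, alpha = alpha))
}

#' Simulate proportional-hazards survival data with known log-HR
#'
#' Calibration fixture for the Cox machinery: a standard-normal exposure,
#' exponential event times with rate `baseline_rate * exp(log_hr * x)`, and
#' administrative censoring at `censor_time` years.
#'
#' @param n sample size.
#' @param log_hr true log hazard ratio per unit of exposure.
#' @param seed integer seed.
#' @param baseline_rate events per year at exposure 0.
#' @param censor_time administrative censoring horizon (years).
#' @return data.frame with `participant`, `time`, `event`, `exposure`.
#' @export
simulateSurvival <- function(n, log_hr, seed = 1L, baseline_rate = 0.08,
                             censor_time = 6.6) {
    set.seed(seed)
    x <- rnorm(n)
    tt <- rexp(n, rate = baseline_rate * exp(log_hr * x))
    data.frame(participant = sprintf("S%05d", seq_len(n)),
               time = pmin(tt, censor_time),
               event = as.integer(tt <= censor_time),
               exposure = x, stringsAsFactors = FALSE)
}
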