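#' Specification of a synthetic ccRCC-like cohort
#'
#' Collects every parameter of the synthetic study: imaging geometry, the
#' two-habitat intensity model, the grade-linked texture effect, survival
#' model, and the planted coexpression structure. The defaults emulate a
#' discovery cohort of 186 patients whose tumors contain a low-density and a
#' high-density voxel population of roughly equal volume, with high-grade
#' tumors showing extra fine-scale texture in the low-density habitat.
#'
#' @param n_patients number of patients.
#' @param image_shape integer triple, voxel grid of each image.
#' @param voxel_spacing numeric triple, mm per voxel.
#' @param habitat_fractions proportions of mask volume assigned to the
#'   low-density and high-density habitat; must sum to 1.
#' @param intensity_means,intensity_sds per-habitat gray-level mean/sd
#'   (arbitrary CT-like units), habitat 1 = low density.
#' @param background_mean,background_sd gray-level distribution of the
#'   surrounding parenchyma (enhancing tissue, between the habitat means).
#' @param texture_sd baseline sd of the spatially correlated texture field
#'   added inside each habitat.
#' @param texture_scale smoothing sigma (voxels) of that texture field.
#' @param grade_effect additive shift of the low-density habitat's texture sd
#'   in high-grade patients; the planted grade signal.
#' @param prevalence_high_grade proportion of high-grade patients.
#' @param survival_baseline_hazard exponential baseline hazard (events per
#'   time unit) at latent risk 0.
#' @param survival_risk_coef log-hazard increase per unit latent risk.
#' @param censoring_max upper bound of the uniform censoring time; `Inf`
#'   disables censoring.
#' @param n_genes total genes in the expression matrix.
#' @param module_sizes sizes of planted coexpression modules (each >= 100).
#' @param module_loading loading of member genes on their module factor.
#' @param module_trait_cor target sample correlation between the first planted
#'   module's factor and the trait (radscore); must lie in (-1, 1).
#' @param noise_sd expression noise sd.
#' @param repeat_perturb probability that a mask boundary voxel is flipped
#'   when emulating re-delineation.
#' @param radius_range min/max tumor semi-axis (mm).
#' @param mean_jitter_sd sd of the per-patient shift of each habitat's
#'   intensity mean (between-patient heterogeneity).
#' @param sd_jitter lognormal sigma of the per-patient multiplier on each
#'   habitat's intensity sd.
#' @param fraction_jitter sd of the per-patient logit jitter of the
#'   low-density habitat fraction.
#' @param texture_jitter lognormal sigma of the per-patient multiplier on the
#'   texture field amplitude.
#' @param seed integer master seed.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_patients = 186L,
                        image_shape = c(28L, 28L, 28L),
                        voxel_spacing = c(1, 1, 1),
                        habitat_fractions = c(0.5, 0.5),
                        intensity_means = c(80, 160),
                        intensity_sds = c(12, 12),
                        background_mean = 95,
                        background_sd = 18,
                        texture_sd = 4,
                        texture_scale = 1.2,
                        grade_effect = 6,
                        prevalence_high_grade = 0.6,
                        survival_baseline_hazard = 0.02,
                        survival_risk_coef = 0.8,
                        censoring_max = 60,
                        n_genes = 600L,
                        module_sizes = c(150L, 120L, 100L),
                        module_loading = 0.8,
                        module_trait_cor = -0.31,
                        noise_sd = 1,
                        repeat_perturb = 0.15,
                        radius_range = c(6, 10),
                        mean_jitter_sd = 6,
                        sd_jitter = 0.15,
                        fraction_jitter = 0.25,
                        texture_jitter = 0.2,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               image_shape = as.integer(image_shape),
               voxel_spacing = as.numeric(voxel_spacing),
               habitat_fractions = habitat_fractions,
               intensity_means = intensity_means,
               intensity_sds = intensity_sds,
               background_mean = background_mean,
               background_sd = background_sd,
               texture_sd = texture_sd,
               texture_scale = texture_scale,
               grade_effect = grade_effect,
               prevalence_high_grade = prevalence_high_grade,
               survival_baseline_hazard = survival_baseline_hazard,
               survival_risk_coef = survival_risk_coef,
               censoring_max = censoring_max,
               n_genes = as.integer(n_genes),
               module_sizes = as.integer(module_sizes),
               module_loading = module_loading,
               module_trait_cor = module_trait_cor,
               noise_sd = noise_sd,
               repeat_perturb = repeat_perturb,
               radius_range = radius_range,
               mean_jitter_sd = mean_jitter_sd,
               sd_jitter = sd_jitter,
               fraction_jitter = fraction_jitter,
               texture_jitter = texture_jitter,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_patients >= 1,
            length(spec$image_shape) == 3, all(spec$image_shape >= 4),
            length(spec$voxel_spacing) == 3, all(spec$voxel_spacing > 0),
            length(spec$habitat_fractions) == 2)
  if (abs(sum(spec$habitat_fractions) - 1) > 1e-8)
    stop("habitat_fractions must sum to 1")
  if (any(spec$intensity_sds <= 0)) stop("intensity_sds must all be positive")
  if (spec$prevalence_high_grade <= 0 || spec$prevalence_high_grade >= 1)
    stop("prevalence_high_grade must lie strictly between 0 and 1")
  if (spec$survival_baseline_hazard <= 0)
    stop("survival_baseline_hazard must be positive")
  if (any(spec$module_sizes < 100))
    stop("module_sizes must each be >= 100 (minimum module size)")
  if (sum(spec$module_sizes) > spec$n_genes)
    stop("module_sizes must sum to at most n_genes")
  if (abs(spec$module_trait_cor) >= 1)
    stop("module_trait_cor must lie strictly inside (-1, 1)")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_patients, "patients,",
      paste(x$image_shape, collapse = "x"), "voxels at",
      paste(x$voxel_spacing, collapse = "x"), "mm\n")
  cat("  habitats: fractions", paste(x$habitat_fractions, collapse = "/"),
      " means", paste(x$intensity_means, collapse = "/"),
      " grade effect", x$grade_effect, "\n")
  cat("  genes:", x$n_genes, " planted modules:",
      paste(x$module_sizes, collapse = "/"),
      " trait cor:", x$module_trait_cor, "\n")
  invisible(x)
}

#' Generate the clinical table of a synthetic cohort
#'
#' Draws grade, TNM stage (correlated with grade), age, sex, laterality and a
#' latent risk score per patient. Survival columns are appended by
#' [generate_survival()].
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per patient, including a `latent_risk`
#'   column (higher in high-grade patients) used to drive survival times.
#' @export
generate_clinical <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_patients
  grade <- ifelse(stats::runif(n) < spec$prevalence_high_grade, "high", "low")
  p_tnm <- ifelse(grade == "high", 0.55, 0.2)
  tnm <- ifelse(stats::runif(n) < p_tnm, "high", "low")
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             grade = grade,
             tnm = tnm,
             age = round(stats::rnorm(n, 60, 11), 1),
             sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.65, 0.35)),
             laterality = sample(c("left", "right"), n, replace = TRUE),
             latent_risk = (grade == "high") + stats::rnorm(n, 0, 0.5),
             stringsAsFactors = FALSE)
}

# Flip a fraction of boundary voxels of a binary mask (random dilation and
# erosion), emulating a re-delineation of the VOI.
perturb_mask <- function(mask, prob) {
  d <- dim(mask)
  m <- mask
  nb <- array(0, d)
  for (dd in 1:3) for (o in c(-1L, 1L)) nb <- nb + shift3d(mask, o, dd)
  inner <- mask == 1 & nb < 6   # mask voxels touching outside
  outer <- mask == 0 & nb > 0   # outside voxels touching mask
  flip_in <- inner & array(stats::runif(length(m)) < prob, d)
  flip_out <- outer & array(stats::runif(length(m)) < prob, d)
  m[flip_in] <- 0
  m[flip_out] <- 1
  # never empty the mask
  if (sum(m) == 0) m <- mask
  m
}

#' Generate one synthetic tumor volume with habitat structure
#'
#' Builds an image volume containing an ellipsoidal tumor whose voxels come
#' from a two-component intensity mixture arranged as spatially contiguous
#' blobs (a smoothed Gaussian field thresholded at the low-density habitat
#' fraction). In high-grade patients the low-density habitat receives extra
#' fine-scale texture (`grade_effect` added to its texture sd). Two perturbed
#' re-delineations of the mask (intra- and inter-observer repeats) are
#' attached.
#'
#' @param spec a [cohort_spec()].
#' @param patient one-row data.frame with at least `patient_id` and `grade`.
#' @return object of class `tumor_volume`: list with `image` (3-D array),
#'   `spacing`, `mask`, `repeat_masks` (list `intra`, `inter`), `habitat_truth`
#'   (planted habitat labels, 0 outside), `patient_id`, `grade`.
#' @export
generate_tumor_volume <- function(spec, patient) {
  validate_cohort_spec(spec)
  if (is.null(patient$grade)) stop("patient must carry a grade label")
  d <- spec$image_shape
  sp <- spec$voxel_spacing
  centre <- d / 2
  radii_mm <- stats::runif(3, spec$radius_range[1], spec$radius_range[2])
  radii_vox <- radii_mm / sp
  over <- which(centre - radii_vox < 1 | centre + radii_vox > d)
  if (length(over))
    stop("tumor mask exceeds image bounds in dimension(s): ",
         paste(c("x", "y", "z")[over], collapse = ", "))
  ax <- (seq_len(d[1]) - centre[1]) / radii_vox[1]
  ay <- (seq_len(d[2]) - centre[2]) / radii_vox[2]
  az <- (seq_len(d[3]) - centre[3]) / radii_vox[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  mask <- array(as.integer(r2 <= 1), d)

  # per-patient random effects: cohorts are heterogeneous, which is what gives
  # the ICC analysis its between-subject variance
  mu_p <- spec$intensity_means + stats::rnorm(2, 0, spec$mean_jitter_sd)
  sd_p <- spec$intensity_sds * exp(stats::rnorm(2, 0, spec$sd_jitter))
  tex_p <- spec$texture_sd * exp(stats::rnorm(1, 0, spec$texture_jitter))
  f1 <- spec$habitat_fractions[1]
  f1 <- stats::plogis(stats::qlogis(f1) + stats::rnorm(1, 0, spec$fraction_jitter))

  # contiguous habitat blobs: smoothed field thresholded at the habitat-1 quantile
  field <- smooth3d(array(stats::rnorm(prod(d)), d), 2)
  thr <- stats::quantile(field[mask == 1], f1)
  habitat <- array(0L, d)
  habitat[mask == 1] <- ifelse(field[mask == 1] <= thr, 1L, 2L)

  tex_field <- smooth3d(array(stats::rnorm(prod(d)), d), spec$texture_scale)
  tex_field <- tex_field / stats::sd(tex_field)
  white <- array(stats::rnorm(prod(d)), d)

  img <- array(stats::rnorm(prod(d), spec$background_mean, spec$background_sd), d)
  high <- identical(as.character(patient$grade), "high")
  for (h in 1:2) {
    sel <- habitat == h
    tsd <- tex_p + if (h == 1 && high) spec$grade_effect else 0
    img[sel] <- mu_p[h] + sd_p[h] * white[sel] + tsd * tex_field[sel]
  }

  rep_intra <- perturb_mask(mask, spec$repeat_perturb)
  rep_inter <- perturb_mask(mask, spec$repeat_perturb)
  structure(list(image = img, spacing = sp, mask = mask,
                 repeat_masks = list(intra = rep_intra, inter = rep_inter),
                 habitat_truth = habitat,
                 patient_id = patient$patient_id %||% "P000",
                 grade = as.character(patient$grade)),
            class = "tumor_volume")
}

#' @export
print.tumor_volume <- function(x, ...) {
  cat("Synthetic tumor volume", x$patient_id, "(grade ", x$grade, "): ",
      paste(dim(x$image), collapse = "x"), " voxels, mask size ",
      sum(x$mask), "\n", sep = "")
  invisible(x)
}

#' Generate survival times from a latent risk score
#'
#' Exponential event times with hazard `baseline * exp(coef * risk)` and
#' independent uniform censoring on `(0, censoring_max)`; `censoring_max = Inf`
#' disables censoring so every record is an event.
#'
#' @param spec a [cohort_spec()].
#' @param latent_risk numeric vector of per-patient risk scores.
#' @return data.frame with `os_time` (> 0) and `os_event` (1 dead, 0 censored).
#' @export
generate_survival <- function(spec, latent_risk) {
  validate_cohort_spec(spec)
  if (any(!is.finite(latent_risk))) stop("latent_risk must be finite")
  n <- length(latent_risk)
  rate <- spec$survival_baseline_hazard * exp(spec$survival_risk_coef * latent_risk)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (is.finite(spec$censoring_max))
    stats::runif(n, 0, spec$censoring_max) else rep(Inf, n)
  os_time <- pmin(t_event, t_cens)
  os_time <- pmax(os_time, .Machine$double.eps)
  data.frame(os_time = os_time, os_event = as.integer(t_event <= t_cens))
}

#' Generate an expression matrix with planted coexpression modules
#'
#' Each planted module m has a latent factor; member genes are
#' `loading * factor + noise`. The first module's factor is constructed to
#' have *exactly* the target sample correlation with the supplied trait
#' (the radscore); the other factors and all background genes are independent
#' noise.
#'
#' @param spec a [cohort_spec()].
#' @param trait numeric per-sample score (e.g. the radscore); its length sets
#'   the number of samples.
#' @param sample_ids optional sample names.
#' @return list with `expr` (genes x samples matrix), `module_truth`
#'   (planted label per gene, "grey" for background) and `factors`.
#' @export
generate_expression <- function(spec, trait, sample_ids = NULL) {
  validate_cohort_spec(spec)
  rho <- spec$module_trait_cor
  n <- length(trait)
  if (n < 3) stop("need at least 3 samples")
  if (stats::sd(trait) == 0) stop("trait is constant; cannot plant a correlation")
  z <- as.numeric(scale(trait))
  nmod <- length(spec$module_sizes)
  factors <- matrix(NA_real_, n, nmod)
  for (m in seq_len(nmod)) {
    e <- stats::rnorm(n)
    e <- stats::residuals(stats::lm(e ~ z))       # orthogonal to the trait
    e <- as.numeric(scale(e))
    factors[, m] <- if (m == 1) rho * z + sqrt(1 - rho^2) * e else e
  }
  labels <- rep("grey", spec$n_genes)
  expr <- matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise_sd), spec$n_genes, n)
  g0 <- 0L
  for (m in seq_len(nmod)) {
    idx <- g0 + seq_len(spec$module_sizes[m])
    expr[idx, ] <- expr[idx, ] +
      spec$module_loading * matrix(factors[, m], length(idx), n, byrow = TRUE)
    labels[idx] <- paste0("planted", m)
    g0 <- g0 + spec$module_sizes[m]
  }
  rownames(expr) <- sprintf("gene%04d", seq_len(spec$n_genes))
  colnames(expr) <- sample_ids %||% sprintf("S%03d", seq_len(n))
  list(expr = expr, module_truth = stats::setNames(labels, rownames(expr)),
       factors = factors)
}

#' Generate a synthetic annotation table for enrichment analysis
#'
#' One term per planted module covering a fraction of its genes (a genuinely
#' enriched term) plus background terms of randomly drawn genes, in the
#' `term_id`/`term_name`/`gene` layout expected by [hypergeom_enrichment()].
#'
#' @param module_truth named planted-module labels from [generate_expression()].
#' @param n_background number of random background terms.
#' @param coverage fraction of each planted module included in its term.
#' @param bg_size gene count per background term.
#' @return data.frame with columns `term_id`, `term_name`, `gene`.
#' @export
generate_annotation <- function(module_truth, n_background = 15L,
                                coverage = 0.6, bg_size = 40L) {
  genes <- names(module_truth)
  rows <- list()
  for (m in setdiff(unique(module_truth), "grey")) {
    mg <- genes[module_truth == m]
    pick <- sample(mg, max(2, round(coverage * length(mg))))
    rows[[m]] <- data.frame(term_id = paste0("T_", m),
                            term_name = paste0("planted pathway ", m),
                            gene = pick, stringsAsFactors = FALSE)
  }
  for (b in seq_len(n_background)) {
    rows[[paste0("bg", b)]] <- data.frame(
      term_id = sprintf("T_bg%02d", b),
      term_name = sprintf("background set %02d", b),
      gene = sample(genes, bg_size), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_clinical()], one [generate_tumor_volume()] per patient and
#' [generate_survival()] under a single master seed (fanned out per patient so
#' any subset is reproducible). Expression is generated later, once a radscore
#' exists, via [generate_expression()].
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `spec`, `clinical`
#'   (including survival columns) and `volumes` (list of `tumor_volume`).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  seeds <- fan_seeds(spec$seed, spec$n_patients + 2L)
  set.seed(seeds[1])
  clinical <- generate_clinical(spec)
  volumes <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    set.seed(seeds[1L + i])
    volumes[[i]] <- generate_tumor_volume(spec, clinical[i, ])
  }
  names(volumes) <- clinical$patient_id
  set.seed(seeds[spec$n_patients + 2L])
  surv <- generate_survival(spec, clinical$latent_risk)
  clinical <- cbind(clinical, surv)
  structure(list(spec = spec, clinical = clinical, volumes = volumes),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$clinical), "patients (",
      sum(x$clinical$grade == "high"), "high-grade ),",
      sum(x$clinical$os_event), "deaths\n")
  invisible(x)
}
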