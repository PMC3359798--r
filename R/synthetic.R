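# Run fn() under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL uses (and advances) the current stream.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

# Normal draws truncated at 0 by inverse-CDF sampling (deterministic under
# a fixed RNG stream). sd = 0 degenerates to the mean.
.rtrunc0norm <- function(n, mean, sd) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (mean < 0) stop("degenerate truncated normal with mean < 0 is infeasible")
    return(rep(mean, n))
  }
  p0 <- stats::pnorm(0, mean, sd)
  if (p0 > 1 - 1e-12)
    stop(sprintf(
      "infeasible truncation: N(%g, %g) has essentially no mass above 0",
      mean, sd))
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

.MODEL_IDS <- c("aif", "blood", "ees", "ies", "tissue", "csfif", "csf_voxel")

#' Generate a (possibly noisy) model concentration curve
#'
#' Evaluates one of the forward models on a time grid and adds i.i.d.
#' zero-mean Gaussian noise of standard deviation `noise_sd` (in mM).
#' Output is reproducible for a fixed seed, and with `noise_sd = 0` it is
#' exactly the noiseless forward curve.
#'
#' @param model_id One of "aif", "blood", "ees", "ies", "tissue", "csfif",
#'   "csf_voxel".
#' @param params A list carrying the parameter objects the model needs:
#'   `blood` ([blood_params]) for the blood-side models, `tissue`
#'   ([tissue_params]) for the tissue models, `csf` ([csf_params]) for the
#'   CSF models.
#' @param time_grid Sampling times in minutes.
#' @param noise_sd Gaussian noise standard deviation in mM (>= 0).
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @return A [concentration_curve].
#' @examples
#' b <- blood_params(0.05, 0.03, 0.45)
#' generate_curve("blood", list(blood = b), seq(0, 60, 2), 0.005, seed = 1)
#' @export
generate_curve <- function(model_id, params, time_grid, noise_sd = 0,
                           seed = NULL) {
  if (!is.character(model_id) || length(model_id) != 1L ||
      !model_id %in% .MODEL_IDS)
    stop("unknown model_id; must be one of: ",
         paste(.MODEL_IDS, collapse = ", "))
  tg <- .check_times(time_grid)
  noise_sd <- .check_scalar(noise_sd, "noise_sd", lower = 0)
  clean <- switch(model_id,
    aif = aif(tg, params$blood),
    blood = blood_concentration(tg, params$blood),
    ees = ees_concentration(tg, params$tissue, params$blood),
    ies = ies_concentration(tg, params$tissue, params$blood),
    tissue = tissue_concentration(tg, params$tissue, params$blood),
    csfif = csf_input_function(tg, params$csf),
    csf_voxel = csf_voxel_concentration(tg, params$csf, params$blood))
  vals <- .with_seed(seed, function() {
    if (noise_sd > 0) clean + stats::rnorm(length(clean), 0, noise_sd)
    else clean
  })
  concentration_curve(tg, vals)
}

#' Specification of a synthetic cohort
#'
#' Defines the study design a synthetic cohort is drawn from: disease
#' stages, CSF regions, subjects per stage, the per-(stage, region)
#' truncated-normal distributions of the kinetic parameters, the sampling
#' grid and the measurement noise. Defaults are seeded from
#' physiologically reported ranges for slow-infusion brain DCE-MRI: blood
#' input rates 0.0427-0.0956 mM/min, blood output rates 0.0281-0.0344
#' 1/min, fractional blood volume of CSF voxels 9.4-16.5%. The CSF
#' evacuation rate `k_out_prime` is centered away from the blood
#' elimination rate (0.045 vs 0.031 1/min): the two describe different
#' physical processes, and near-equal decay rates would make the blood
#' and CSF input shapes proportional, collapsing `v_blood` and
#' `k_in_prime` onto a single identifiable combination.
#'
#' Per-subject parameters are drawn independently from normals truncated
#' at 0 (fractions additionally capped at 1); the distributions are the
#' same for all stages unless the `rate_table` rows are edited, e.g. via
#' [scale_stage()].
#'
#' @param n_per_stage Subjects per stage (>= 1).
#' @param stages Character vector of stage labels; must include `control`.
#' @param regions Character vector of CSF region labels.
#' @param control Label of the control (normal-brain) stage.
#' @param time_start,time_stop,time_step Sampling grid in minutes.
#' @param noise_sd Measurement noise standard deviation in mM.
#' @param hct Hematocrit applied to every subject.
#' @param rate_table Optional data.frame with one row per (stage, region)
#'   and columns `<param>_mean` / `<param>_sd` for `c_in`, `k_out`,
#'   `k_in_prime`, `k_out_prime`, `v_blood`; `NULL` builds the default.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_stage = 10L,
                        stages = c("control", "mild", "severe"),
                        regions = "lateral_ventricle",
                        control = "control",
                        time_start = 0, time_stop = 60, time_step = 1,
                        noise_sd = 0.005, hct = 0.45,
                        rate_table = NULL) {
  n_per_stage <- as.integer(n_per_stage)
  if (is.na(n_per_stage) || n_per_stage < 1L)
    stop("n_per_stage must be >= 1")
  stopifnot(is.character(stages), length(stages) >= 1L,
            is.character(regions), length(regions) >= 1L)
  if (!control %in% stages)
    stop(sprintf("control stage '%s' is not among the stages", control))
  if (time_step <= 0 || time_stop <= time_start || time_start < 0)
    stop("invalid time grid")
  noise_sd <- .check_scalar(noise_sd, "noise_sd", lower = 0)
  hct <- .check_scalar(hct, "hct", lower = 0, upper = 1)
  if (is.null(rate_table)) {
    rate_table <- expand.grid(stage = stages, region = regions,
                              stringsAsFactors = FALSE)
    defaults <- c(c_in_mean = 0.06, c_in_sd = 0.008,
                  k_out_mean = 0.031, k_out_sd = 0.0025,
                  k_in_prime_mean = 0.06, k_in_prime_sd = 0.008,
                  k_out_prime_mean = 0.045, k_out_prime_sd = 0.004,
                  v_blood_mean = 0.12, v_blood_sd = 0.02)
    for (nmv in names(defaults)) rate_table[[nmv]] <- defaults[[nmv]]
  } else {
    need <- c("stage", "region",
              paste0(rep(c("c_in", "k_out", "k_in_prime", "k_out_prime",
                           "v_blood"), each = 2), c("_mean", "_sd")))
    miss <- setdiff(need, names(rate_table))
    if (length(miss))
      stop("rate_table misses columns: ", paste(miss, collapse = ", "))
  }
  structure(list(n_per_stage = n_per_stage, stages = stages,
                 regions = regions, control = control,
                 time_start = time_start, time_stop = time_stop,
                 time_step = time_step, noise_sd = noise_sd, hct = hct,
                 rate_table = rate_table),
            class = "cohort_spec")
}

#' Scale a parameter distribution of one cohort stage
#'
#' Multiplies the mean (and sd, keeping the coefficient of variation) of
#' one kinetic parameter in every region of one stage — the standard way
#' to encode a disease effect such as a doubled CSF input rate in the mild
#' stage.
#'
#' @param spec A [cohort_spec].
#' @param stage Stage label to modify.
#' @param param One of "c_in", "k_out", "k_in_prime", "k_out_prime",
#'   "v_blood".
#' @param factor Positive multiplier.
#' @return The modified `cohort_spec`.
#' @export
scale_stage <- function(spec, stage, param, factor) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!stage %in% spec$stages) stop("unknown stage: ", stage)
  param <- match.arg(param, c("c_in", "k_out", "k_in_prime",
                              "k_out_prime", "v_blood"))
  factor <- .check_scalar(factor, "factor", lower = 0, strict_lower = TRUE)
  sel <- spec$rate_table$stage == stage
  spec$rate_table[sel, paste0(param, "_mean")] <-
    spec$rate_table[sel, paste0(param, "_mean")] * factor
  spec$rate_table[sel, paste0(param, "_sd")] <-
    spec$rate_table[sel, paste0(param, "_sd")] * factor
  spec
}

#' Generate a synthetic cohort of blood and CSF curves
#'
#' Draws per-subject true kinetic parameters from the spec's truncated
#' normal distributions, then emits for each subject a blood-ROI curve
#' (region "blood_pool") and one CSF-voxel curve per region, all with
#' additive Gaussian noise of the spec's `noise_sd`. The returned truth
#' table supports recovery experiments. Identical spec and seed give
#' bit-identical output.
#'
#' @param spec A [cohort_spec].
#' @param seed Integer seed.
#' @return A list of class `dcekin_cohort` with elements `truth` (one row
#'   per subject and region with the generating parameters), `curves`
#'   (long data.frame: `subject`, `region`, `stage`, `roi`, `time_min`,
#'   `conc_mM`) and `spec`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  tg <- seq(spec$time_start, spec$time_stop, by = spec$time_step)
  .with_seed(seed, function() {
    truth <- list(); curves <- list()
    for (stage in spec$stages) {
      for (i in seq_len(spec$n_per_stage)) {
        subject <- sprintf("%s_%03d", stage, i)
        rt0 <- spec$rate_table[spec$rate_table$stage == stage, ,
                               drop = FALSE][1L, ]
        bp <- blood_params(
          c_in = .rtrunc0norm(1, rt0$c_in_mean, rt0$c_in_sd),
          k_out = max(.rtrunc0norm(1, rt0$k_out_mean, rt0$k_out_sd), 1e-6),
          hct = spec$hct)
        bvals <- blood_concentration(tg, bp)
        if (spec$noise_sd > 0)
          bvals <- bvals + stats::rnorm(length(tg), 0, spec$noise_sd)
        curves[[length(curves) + 1L]] <- data.frame(
          subject = subject, region = "blood_pool", stage = stage,
          roi = "blood", time_min = tg, conc_mM = bvals,
          stringsAsFactors = FALSE)
        for (region in spec$regions) {
          rt <- spec$rate_table[spec$rate_table$stage == stage &
                                  spec$rate_table$region == region, ,
                                drop = FALSE]
          if (nrow(rt) != 1L)
            stop(sprintf("rate_table needs exactly one row for (%s, %s)",
                         stage, region))
          cp <- csf_params(
            k_in_prime = .rtrunc0norm(1, rt$k_in_prime_mean,
                                      rt$k_in_prime_sd),
            k_out_prime = max(.rtrunc0norm(1, rt$k_out_prime_mean,
                                           rt$k_out_prime_sd), 1e-6),
            v_blood = min(.rtrunc0norm(1, rt$v_blood_mean, rt$v_blood_sd), 1))
          truth[[length(truth) + 1L]] <- data.frame(
            subject = subject, region = region, stage = stage,
            c_in = bp$c_in, k_out = bp$k_out, hct = bp$hct,
            k_in_prime = cp$k_in_prime, k_out_prime = cp$k_out_prime,
            v_blood = cp$v_blood, stringsAsFactors = FALSE)
          cvals <- csf_voxel_concentration(tg, cp, bp)
          if (spec$noise_sd > 0)
            cvals <- cvals + stats::rnorm(length(tg), 0, spec$noise_sd)
          curves[[length(curves) + 1L]] <- data.frame(
            subject = subject, region = region, stage = stage,
            roi = "csf", time_min = tg, conc_mM = cvals,
            stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(truth = do.call(rbind, truth),
                   curves = do.call(rbind, curves),
                   spec = spec),
              class = "dcekin_cohort")
  })
}

#' @export
print.dcekin_cohort <- function(x, ...) {
  cat(sprintf("<dcekin_cohort: %d stages x %d subjects, %d CSF region(s), %d curve samples>\n",
              length(x$spec$stages), x$spec$n_per_stage,
              length(x$spec$regions), nrow(x$curves)))
  invisible(x)
}

#' Generate a 4D digital phantom
#'
#' Builds a small 4D concentration image from a voxel-class layout: each
#' voxel is "background" (always 0), "blood", "tissue" or "csf" and
#' follows the corresponding forward model with the class's parameters,
#' plus optional Gaussian noise. Per-parameter 3D truth maps accompany the
#' image.
#'
#' @param layout A list with `dim` (length-3 integer), `classes` (array of
#'   the given dim with values among "background", "blood", "tissue",
#'   "csf") and `params` (list with [blood_params] `blood` and, when the
#'   corresponding classes occur, [tissue_params] `tissue` and
#'   [csf_params] `csf`).
#' @param time_grid Sampling times in minutes.
#' @param noise_sd Gaussian noise sd in mM.
#' @param seed Optional integer seed.
#' @return A list of class `dcekin_phantom`: `image` (4D array
#'   x-y-z-time), `truth` (list of 3D maps: `class`, `k_trans`,
#'   `v_blood`, `k_in_prime`), `times`.
#' @export
generate_phantom <- function(layout, time_grid, noise_sd = 0, seed = NULL) {
  stopifnot(is.list(layout), !is.null(layout$dim), !is.null(layout$classes))
  dm <- as.integer(layout$dim)
  if (length(dm) != 3L || any(dm < 1L)) stop("layout$dim must be 3 positive integers")
  classes <- layout$classes
  if (!identical(dim(classes), dm) && length(classes) != prod(dm))
    stop("layout$classes does not match layout$dim")
  classes <- array(as.character(classes), dim = dm)
  known <- c("background", "blood", "tissue", "csf")
  if (!all(classes %in% known))
    stop("unknown voxel class; allowed: ", paste(known, collapse = ", "))
  tg <- .check_times(time_grid)
  nt <- length(tg)
  pr <- layout$params
  series <- list(background = numeric(nt))
  if (any(classes == "blood"))
    series$blood <- blood_concentration(tg, pr$blood)
  if (any(classes == "tissue"))
    series$tissue <- tissue_concentration(tg, pr$tissue, pr$blood)
  if (any(classes == "csf"))
    series$csf <- csf_voxel_concentration(tg, pr$csf, pr$blood)
  img <- array(0, dim = c(dm, nt))
  truth <- list(class = classes,
                k_trans = array(NA_real_, dm),
                v_blood = array(NA_real_, dm),
                k_in_prime = array(NA_real_, dm))
  .with_seed(seed, function() {
    for (ix in seq_len(dm[1L])) for (iy in seq_len(dm[2L]))
      for (iz in seq_len(dm[3L])) {
        cl <- classes[ix, iy, iz]
        ts <- series[[cl]]
        if (cl != "background" && noise_sd > 0)
          ts <- ts + stats::rnorm(nt, 0, noise_sd)
        img[ix, iy, iz, ] <- ts
        if (cl == "tissue") {
          truth$k_trans[ix, iy, iz] <<- pr$tissue$k_trans
          truth$v_blood[ix, iy, iz] <<- pr$tissue$v_blood
        } else if (cl == "csf") {
          truth$k_in_prime[ix, iy, iz] <<- pr$csf$k_in_prime
          truth$v_blood[ix, iy, iz] <<- pr$csf$v_blood
        } else if (cl == "blood") {
          truth$v_blood[ix, iy, iz] <<- 1
        }
      }
    structure(list(image = img, truth = truth, times = tg),
              class = "dcekin_phantom")
  })
}

#' Write a phantom as NIfTI-1 volumes
#'
#' Exports the 4D concentration image (time step recorded in the temporal
#' pixdim) and the 3D truth maps as NIfTI files under `dir`.
#'
#' @param phantom A `dcekin_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "dcekin_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dt <- if (length(phantom$times) > 1L) diff(phantom$times)[1L] else 1
  files <- character()
  f <- file.path(dir, "phantom_4d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(phantom$image,
                                     pixdim = c(1, 1, 1, dt)), f)
  files <- c(files, f)
  for (nm in c("k_trans", "v_blood", "k_in_prime")) {
    f <- file.path(dir, sprintf("truth_%s.nii.gz", nm))
    RNifti::writeNifti(RNifti::asNifti(phantom$truth[[nm]]), f)
    files <- c(files, f)
  }
  invisible(files)
}
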