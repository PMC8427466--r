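#' Cohort-level generator configuration
#'
#' Per-group distributions from which simulated animals are drawn. Printed
#' group summaries in the source study are means +/- standard errors, so the
#' defaults here convert SEs to SDs with sqrt(n) (n = 10 sham, n = 9 BDL at
#' baseline; n = 7 BDL completed the post-endotoxin time point).
#'
#' Baseline defaults: sham perfusion 316 +/- 24 SE (SD 75.9), liver T1
#' 1256 +/- 18 (SD 56.9), liver weight 14 +/- 1 (SD 3.2); BDL perfusion
#' 199 +/- 32 (SD 96), T1 1533 +/- 50 (SD 150), weight 30 +/- 2 (SD 6).
#' Post-endotoxin perfusion shifts: sham +78 +/- 33 (SD 104.4), BDL
#' -49 +/- 40 (SD 105.8); T1 shifts sham +0.2 +/- 9 (SD 28.5), BDL
#' +14 +/- 11 (SD 29.1). BDL attrition probability 2/9.
#'
#' The per-animal bulk-flow (TLBF) ground truth is generated as perfusion
#' plus a method-difference offset, emulating the observed FAIR-vs-PCMRI
#' disagreement: sham offset +144 (TLBF above perfusion), BDL -54, with SDs
#' back-computed from the per-cohort 95% limits of agreement (157/1.96,
#' 181/1.96).
#'
#' @param n_sham,n_bdl group sizes.
#' @param sham_perfusion,bdl_perfusion c(mean, sd) baseline perfusion,
#'   ml/min/100 g.
#' @param sham_t1,bdl_t1 c(mean, sd) baseline liver T1, ms.
#' @param sham_weight,bdl_weight c(mean, sd) wet liver weight, g.
#' @param sham_lps_perfusion,bdl_lps_perfusion c(mean, sd) additive
#'   post-endotoxin perfusion shift, ml/min/100 g.
#' @param sham_lps_t1,bdl_lps_t1 c(mean, sd) additive post-endotoxin T1
#'   shift, ms.
#' @param sham_tlbf_offset,bdl_tlbf_offset c(mean, sd) of TLBF minus
#'   perfusion, ml/min/100 g.
#' @param attrition_probability_bdl probability a BDL animal is lost before
#'   the post-endotoxin measurement.
#' @param seed default seed used by [build_cohort()].
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_sham = 10L, n_bdl = 9L,
                          sham_perfusion = c(316, 24 * sqrt(10)),
                          bdl_perfusion = c(199, 32 * sqrt(9)),
                          sham_t1 = c(1256, 18 * sqrt(10)),
                          bdl_t1 = c(1533, 50 * sqrt(9)),
                          sham_weight = c(14, 1 * sqrt(10)),
                          bdl_weight = c(30, 2 * sqrt(9)),
                          sham_lps_perfusion = c(78, 33 * sqrt(10)),
                          bdl_lps_perfusion = c(-49, 40 * sqrt(7)),
                          sham_lps_t1 = c(0.2, 9 * sqrt(10)),
                          bdl_lps_t1 = c(14, 11 * sqrt(7)),
                          sham_tlbf_offset = c(144, 157 / 1.96),
                          bdl_tlbf_offset = c(-54, 181 / 1.96),
                          attrition_probability_bdl = 2 / 9,
                          seed = 1L) {
  if (n_sham < 1 || n_bdl < 1) {
    stop("group sizes must be at least 1", call. = FALSE)
  }
  pars <- list(sham_perfusion = sham_perfusion, bdl_perfusion = bdl_perfusion,
               sham_t1 = sham_t1, bdl_t1 = bdl_t1,
               sham_weight = sham_weight, bdl_weight = bdl_weight,
               sham_lps_perfusion = sham_lps_perfusion,
               bdl_lps_perfusion = bdl_lps_perfusion,
               sham_lps_t1 = sham_lps_t1, bdl_lps_t1 = bdl_lps_t1,
               sham_tlbf_offset = sham_tlbf_offset,
               bdl_tlbf_offset = bdl_tlbf_offset)
  for (nm in names(pars)) {
    p <- pars[[nm]]
    if (length(p) != 2L || !all(is.finite(p)) || p[2] < 0) {
      stop(sprintf("`%s` must be c(mean, sd) with sd >= 0", nm), call. = FALSE)
    }
  }
  if (attrition_probability_bdl < 0 || attrition_probability_bdl > 1) {
    stop("attrition_probability_bdl must lie in [0, 1]", call. = FALSE)
  }
  structure(c(list(n_sham = as.integer(n_sham), n_bdl = as.integer(n_bdl)),
              pars,
              list(attrition_probability_bdl = attrition_probability_bdl,
                   seed = as.integer(seed))),
            class = "cohort_config")
}

draw_group <- function(n, mean_sd) {
  stats::rnorm(n, mean_sd[1], mean_sd[2])
}

#' Simulate a study cohort of digital animals
#'
#' Draws per-animal baseline parameters (perfusion, liver T1, liver weight,
#' TLBF offset) and post-endotoxin shifts from the group distributions in
#' `config`, builds one [phantom_spec()] per animal, and flags BDL animals
#' lost before the post-endotoxin time point. Perfusion draws are truncated
#' at zero (perfusion cannot be negative).
#'
#' @param config a [cohort_config()].
#' @param seed integer; overrides `config$seed`.
#' @param grid_shape matrix size passed to [phantom_spec()].
#' @return list of `phantom_spec` objects; each carries `$animal_id`,
#'   `$lost_post_lps`, `$lps_perfusion_shift`, `$lps_t1_shift` and
#'   `$tlbf_true` fields.
#' @export
build_cohort <- function(config = cohort_config(), seed = config$seed,
                         grid_shape = c(128L, 128L)) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    groups <- list(
      sham = list(n = config$n_sham, perf = config$sham_perfusion,
                  t1 = config$sham_t1, wt = config$sham_weight,
                  lps_p = config$sham_lps_perfusion,
                  lps_t1 = config$sham_lps_t1,
                  tlbf = config$sham_tlbf_offset, attr = 0),
      BDL = list(n = config$n_bdl, perf = config$bdl_perfusion,
                 t1 = config$bdl_t1, wt = config$bdl_weight,
                 lps_p = config$bdl_lps_perfusion,
                 lps_t1 = config$bdl_lps_t1,
                 tlbf = config$bdl_tlbf_offset,
                 attr = config$attrition_probability_bdl)
    )
    cohort <- list()
    id <- 0L
    for (g in names(groups)) {
      gp <- groups[[g]]
      perf <- pmax(0, draw_group(gp$n, gp$perf))
      t1 <- pmax(200, draw_group(gp$n, gp$t1))
      wt <- pmax(1, draw_group(gp$n, gp$wt))
      tlbf <- pmax(0, perf + draw_group(gp$n, gp$tlbf))
      lps_p <- draw_group(gp$n, gp$lps_p)
      lps_t1 <- draw_group(gp$n, gp$lps_t1)
      lost <- stats::runif(gp$n) < gp$attr
      for (i in seq_len(gp$n)) {
        id <- id + 1L
        ph <- phantom_spec(grid_shape = grid_shape,
                           t1_liver_ms = t1[i], perfusion_liver = perf[i],
                           liver_weight_g = wt[i], tlbf_true = tlbf[i],
                           cohort = g, seed = child_seed(seed, id))
        ph$animal_id <- sprintf("%s_%02d", tolower(g), i)
        ph$lost_post_lps <- lost[i]
        ph$lps_perfusion_shift <- lps_p[i]
        ph$lps_t1_shift <- lps_t1[i]
        ph$tlbf_true <- tlbf[i]
        cohort[[id]] <- ph
      }
    }
    cohort
  })
}

#' Apply the post-endotoxin parameter shift to a phantom
#'
#' The inflammatory challenge is modelled as a pure additive shift of liver
#' perfusion and tissue T1 drawn at cohort-generation time (a single
#' post-challenge snapshot; no within-acquisition dynamics). Shifted
#' perfusion is truncated at zero.
#'
#' @param phantom a phantom from [build_cohort()].
#' @return a new `phantom_spec` at the post-endotoxin time point.
#' @export
apply_lps_shift <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (is.null(phantom$lps_perfusion_shift)) {
    stop("phantom has no stored post-endotoxin shifts (not from build_cohort)",
         call. = FALSE)
  }
  post <- phantom
  post$perfusion_true[["liver"]] <-
    max(0, phantom$perfusion_true[["liver"]] + phantom$lps_perfusion_shift)
  post$tissue_t1[["liver"]] <-
    max(200, phantom$tissue_t1[["liver"]] + phantom$lps_t1_shift)
  post$timepoint <- "post_lps"
  post
}

#' Cohort ground-truth table
#'
#' @param cohort list of phantoms from [build_cohort()].
#' @return data.frame with one row per animal (id, cohort, baseline
#'   perfusion/T1/weight, TLBF, shifts, attrition flag).
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(ph) {
    data.frame(animal = ph$animal_id %||% NA_character_,
               cohort = ph$cohort,
               perfusion = ph$perfusion_true[["liver"]],
               t1 = ph$tissue_t1[["liver"]],
               liver_weight = ph$liver_weight_g,
               tlbf = ph$tlbf_true %||% NA_real_,
               lps_perfusion_shift = ph$lps_perfusion_shift %||% NA_real_,
               lps_t1_shift = ph$lps_t1_shift %||% NA_real_,
               lost_post_lps = isTRUE(ph$lost_post_lps))
  }))
}
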