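# End-to-end study orchestration: selection -> harmonisation -> estimation
# -> sensitivity -> model averaging -> multivariable MR, with a structured
# report.

#' Build a validated study configuration
#'
#' Collects every threshold and seed of the analysis pipeline in one
#' self-documenting object. Defaults are the workflow's reference values:
#' genome-wide significance 5e-8, LD pruning at r-squared 0.01, proxies at
#' r-squared above 0.8, weak-instrument bound F = 10, model-averaging
#' priors 0.1 / 0.5, per-variant outlier cut-off Q = 10 and best-model
#' threshold PP = 0.02.
#'
#' @param exposures Named list of exposure inputs: either file paths or
#'   summary-statistic tibbles. Ignored when `fixture = "iron_hf"`.
#' @param outcome Outcome input (path or tibble). Ignored for the fixture.
#' @param fixture `"none"` (default) or `"iron_hf"` to analyse the
#'   packaged iron-status / heart-failure instrument table.
#' @param p_select,ld_r2,proxy_r2,f_min Selection thresholds.
#' @param alpha Nominal significance level echoed in the report.
#' @param prior_prob,sigma,pp_threshold,q_max Model-averaging controls.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param n_perm Permutations for model-averaging p-values (0 disables).
#' @param seed RNG seed for every stochastic stage (mandatory).
#' @param ld_matrix Optional LD r-squared matrix (or path) used for
#'   pruning and proxy search.
#' @param common_snp_analysis,full_set_analysis Which univariable
#'   analyses to run: instruments shared by all exposures, the full
#'   per-exposure sets, or both (both by default).
#' @param run_mvmr Whether to fit the multivariable IVW model.
#' @param drop_palindromic Remove palindromic SNPs during harmonisation.
#' @param binary_exposure Set by [run_binary_exposure_mr()]; adds the
#'   dichotomous-exposure caveat to the report.
#' @return An object of class `study_config`.
#' @export
study_config <- function(exposures = NULL, outcome = NULL,
                         fixture = c("none", "iron_hf"),
                         p_select = 5e-8, ld_r2 = 0.01, proxy_r2 = 0.8,
                         f_min = 10, alpha = 0.05,
                         prior_prob = 0.1, sigma = 0.5,
                         pp_threshold = 0.02, q_max = 10,
                         n_boot = 5000, n_perm = 0, seed,
                         ld_matrix = NULL,
                         common_snp_analysis = TRUE,
                         full_set_analysis = TRUE,
                         run_mvmr = TRUE,
                         drop_palindromic = TRUE,
                         binary_exposure = FALSE) {
  fixture <- match.arg(fixture)
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  assert_scalar_prob(p_select, "p_select")
  assert_scalar_prob(ld_r2, "ld_r2", open_left = FALSE)
  assert_scalar_prob(proxy_r2, "proxy_r2", open_left = FALSE)
  assert_scalar_prob(alpha, "alpha")
  assert_scalar_prob(prior_prob, "prior_prob")
  assert_scalar_prob(pp_threshold, "pp_threshold", open_left = FALSE)
  if (f_min < 0) abort("`f_min` must be non-negative")
  if (q_max <= 0) abort("`q_max` must be positive")
  if (sigma <= 0) abort("`sigma` must be positive")
  if (fixture == "none" && (is.null(exposures) || is.null(outcome))) {
    abort("supply `exposures` and `outcome`, or choose a fixture")
  }
  structure(list(exposures = exposures, outcome = outcome,
                 fixture = fixture, p_select = p_select, ld_r2 = ld_r2,
                 proxy_r2 = proxy_r2, f_min = f_min, alpha = alpha,
                 prior_prob = prior_prob, sigma = sigma,
                 pp_threshold = pp_threshold, q_max = q_max,
                 n_boot = n_boot, n_perm = n_perm, seed = seed,
                 ld_matrix = ld_matrix,
                 common_snp_analysis = common_snp_analysis,
                 full_set_analysis = full_set_analysis,
                 run_mvmr = run_mvmr,
                 drop_palindromic = drop_palindromic,
                 binary_exposure = binary_exposure),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys are [study_config()]
#'   arguments.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  do.call(study_config, yaml::read_yaml(path))
}

# accept either a path or an in-memory tibble
resolve_table <- function(x, trait = NULL) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(sprintf("input file not found: %s", x))
    read_summary_table(x, trait = trait)
  } else if (is.data.frame(x)) {
    validate_gwas(x)
    tibble::as_tibble(x)
  } else {
    abort("inputs must be file paths or data frames")
  }
}

config_echo <- function(config) {
  scalar <- config[!names(config) %in% c("exposures", "outcome", "ld_matrix")]
  scalar <- lapply(scalar, function(v) if (is.null(v)) NA else v)
  tibble::tibble(setting = names(scalar),
                 value = unname(vapply(scalar,
                                       function(v) paste(format(v), collapse = ","),
                                       character(1))))
}

#' Run the full two-sample MR study pipeline
#'
#' Executes the end-to-end workflow on the configured inputs: instrument
#' selection (significance threshold, optional LD pruning), harmonisation
#' with the outcome (palindrome handling, optional proxies), the
#' weak-instrument filter, the univariable estimator suite on the shared
#' instruments and/or the full per-exposure sets, the sensitivity suite
#' (Cochran's Q, leave-one-out, funnel coordinates), model averaging with
#' iterative instrument exclusion, and (optionally) multivariable IVW.
#' Identical configurations and seeds reproduce every number exactly.
#'
#' @param config A [study_config()].
#' @return An object of class `study_report`: a list of tibbles
#'   (`estimates`, `heterogeneity`, `leave_one_out`, `funnel`,
#'   `bma_panels`, `bma_excluded`, `bma_diagnostics`, `mvmr`,
#'   `selection_log`, `instrument_counts`, `config`, `versions`) plus the
#'   fitted objects in `fits`.
#' @export
#' @examples
#' report <- run_study(study_config(fixture = "iron_hf", seed = 1,
#'                                  n_boot = 200))
#' report$estimates
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("study pipeline failed at stage `%s`: %s",
                    name, conditionMessage(e)))
    })
  }

  r2_matrix <- stage("ld_matrix", {
    if (is.character(config$ld_matrix)) read_ld_matrix(config$ld_matrix)
    else config$ld_matrix
  })

  exposures <- stage("read_exposures", {
    if (config$fixture == "iron_hf") {
      sets <- lapply(names(IRON_BIOMARKERS), iron_hf_exposure)
      names(sets) <- names(IRON_BIOMARKERS)
      sets
    } else {
      if (is.null(names(config$exposures))) {
        abort("`exposures` must be a named list")
      }
      purrr::imap(config$exposures, function(x, nm) resolve_table(x, trait = nm))
    }
  })
  outcome <- stage("read_outcome", {
    if (config$fixture == "iron_hf") iron_hf_outcome()
    else resolve_table(config$outcome, trait = "outcome")
  })

  instruments <- stage("selection_harmonisation", {
    purrr::imap(exposures, function(ex, nm) {
      sel <- select_instruments(ex, config$p_select)
      if (!is.null(r2_matrix)) sel <- ld_prune(sel, r2_matrix, config$ld_r2)
      h <- harmonise(sel, outcome,
                     drop_palindromic = config$drop_palindromic,
                     r2_matrix = r2_matrix, proxy_r2 = config$proxy_r2,
                     exposure_name = nm)
      filter_weak(h, config$f_min)
    })
  })

  common_snps <- Reduce(intersect, lapply(instruments, `[[`, "snp_id"))
  analysis_sets <- list()
  if (config$full_set_analysis) {
    analysis_sets <- c(analysis_sets, setNames(
      lapply(instruments, function(x) list(set = x, scope = "full_set")),
      paste0(names(instruments), ".full_set")))
  }
  if (config$common_snp_analysis && length(common_snps) >= 1) {
    analysis_sets <- c(analysis_sets, setNames(
      lapply(instruments, function(x) {
        list(set = x[x$snp_id %in% common_snps, , drop = FALSE],
             scope = "common_snps")
      }),
      paste0(names(instruments), ".common_snps")))
  }

  estimates <- stage("univariable_mr", {
    purrr::map_dfr(analysis_sets, function(a) {
      est <- mr_estimates(a$set, n_boot = config$n_boot, seed = config$seed)
      dplyr::mutate(est, scope = a$scope, .after = "exposure")
    })
  })

  heterogeneity <- stage("heterogeneity", {
    purrr::map_dfr(instruments, function(x) {
      g <- glance(cochran_q(x))
      dplyr::mutate(g, exposure = x$exposure[1], .before = 1)
    })
  })
  loo <- stage("leave_one_out", {
    purrr::map_dfr(instruments, function(x) {
      dplyr::mutate(leave_one_out(x), exposure = x$exposure[1], .before = 1)
    })
  })
  funnel <- stage("funnel", {
    purrr::map_dfr(instruments, function(x) {
      dplyr::mutate(funnel_data(x), exposure = x$exposure[1], .before = 1)
    })
  })

  bma <- stage("model_averaging", {
    wide <- bma_input(instruments)
    trail <- mr_bma_exclude(wide, names(instruments),
                            prior_prob = config$prior_prob,
                            sigma = config$sigma,
                            pp_threshold = config$pp_threshold,
                            q_max = config$q_max)
    panels <- tidy(trail)
    if (config$n_perm > 0) {
      perms <- purrr::map_dfr(seq_along(trail$stages), function(i) {
        p <- bma_permutation_p(trail$stages[[i]], n_perm = config$n_perm,
                               seed = config$seed + i)
        dplyr::mutate(p, stage = i)
      })
      panels <- dplyr::left_join(panels, perms[, c("factor", "stage", "perm_p")],
                                 by = c("factor", "stage"))
    }
    diagnostics <- purrr::map_dfr(seq_along(trail$diagnostics), function(i) {
      dplyr::mutate(trail$diagnostics[[i]], stage = i, .before = 1)
    })
    list(trail = trail, panels = panels, diagnostics = diagnostics)
  })

  mvmr_fit <- NULL
  mvmr_tbl <- tibble::tibble()
  if (config$run_mvmr && length(instruments) >= 2) {
    mvmr_fit <- stage("mvmr", {
      mvmr_ivw(bma_input(instruments), names(instruments))
    })
    mvmr_tbl <- dplyr::mutate(tidy(mvmr_fit),
                              condition_number = mvmr_fit$condition_number,
                              vif = unname(mvmr_fit$vif))
  }

  sel_log <- purrr::map_dfr(instruments, function(x) {
    dplyr::mutate(selection_log(x), exposure = x$exposure[1], .before = 1)
  })
  counts <- tibble::tibble(
    exposure = names(instruments),
    n_input = unname(vapply(exposures, nrow, integer(1))),
    n_retained = unname(vapply(instruments, nrow, integer(1))),
    n_removed = unname(vapply(instruments, function(x) nrow(selection_log(x)),
                              integer(1))))

  report <- list(
    estimates = estimates,
    heterogeneity = heterogeneity,
    leave_one_out = loo,
    funnel = funnel,
    bma_panels = bma$panels,
    bma_excluded = bma$trail$excluded,
    bma_diagnostics = bma$diagnostics,
    mvmr = mvmr_tbl,
    selection_log = sel_log,
    instrument_counts = counts,
    common_snps = common_snps,
    config = config_echo(config),
    caveats = if (config$binary_exposure) {
      paste("The exposure is a dichotomous disease trait; causal estimates",
            "reflect liability-scale shifts among genetically susceptible",
            "individuals and competing-risk bias cannot be excluded.")
    } else character(0),
    versions = tibble::tibble(
      component = c("ironmr", "R"),
      version = c(as.character(packageVersion("ironmr")),
                  paste(R.version$major, R.version$minor, sep = "."))),
    fits = list(instruments = instruments, bma_trail = bma$trail,
                mvmr = mvmr_fit))
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$instrument_counts)
  if (length(x$caveats) > 0) cat("caveat:", x$caveats, "\n")
  cat("\nunivariable estimates:\n")
  print(x$estimates, n = Inf)
  invisible(x)
}

#' Two-sample MR with a dichotomous disease exposure
#'
#' Runs the same univariable pipeline for exposures that are disease
#' states (e.g. hereditary haemochromatosis or iron-deficiency anaemia)
#' rather than quantitative biomarkers. Because a 0/1 exposure violates
#' the homogeneity interpretation of the Wald ratio, the report carries a
#' prominent caveat banner. Input files must exist up front: nothing is
#' written or returned for missing inputs.
#'
#' @inheritParams run_study
#' @return A `study_report` with the `caveats` field set.
#' @export
run_binary_exposure_mr <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (config$fixture != "none") {
    abort("binary-exposure analysis requires user-supplied disease GWAS tables")
  }
  paths <- c(Filter(is.character, config$exposures),
             if (is.character(config$outcome)) config$outcome)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    abort(sprintf("input file(s) not found: %s",
                  paste(unlist(missing), collapse = ", ")))
  }
  config$binary_exposure <- TRUE
  config$run_mvmr <- FALSE
  run_study(config)
}

#' Write a study report to disk
#'
#' Serialises every table of a [run_study()] report as TSV, the whole
#' report as JSON, and a MANIFEST listing the files written. Identical
#' reports produce byte-identical files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("estimates", "heterogeneity", "leave_one_out", "funnel",
              "bma_panels", "bma_excluded", "bma_diagnostics", "mvmr",
              "selection_log", "instrument_counts", "config", "versions")
  paths <- character(0)
  for (nm in tables) {
    tbl <- report[[nm]]
    if (is.null(tbl) || nrow(tbl) == 0) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tbl, p)
    paths <- c(paths, p)
  }
  pj <- file.path(dir, "report.json")
  json_body <- report[setdiff(names(report), "fits")]
  jsonlite::write_json(json_body, pj, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- c(paths, pj)
  manifest <- file.path(dir, "MANIFEST")
  writeLines(c("complete", basename(paths)), manifest)
  invisible(c(paths, manifest))
}
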