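# Packaged instrument fixture: four iron-status biomarkers vs heart failure.

IRON_BIOMARKERS <- c(ferritin = "iron_status_ferritin.tsv",
                     iron = "iron_status_iron.tsv",
                     transferrin = "iron_status_transferrin.tsv",
                     ts = "iron_status_transferrin_saturation.tsv")

fixture_path <- function(file) {
  system.file("extdata", file, package = "ironmr", mustWork = TRUE)
}

#' Packaged exposure summary statistics for the iron-status biomarkers
#'
#' Genome-wide significant instruments for ferritin (6 SNPs), serum iron
#' (5), transferrin (9) and transferrin saturation (5) from the Iron
#' Status Genetics Consortium meta-analysis (48,972 Europeans); 12 unique
#' SNPs in total, of which rs1800562, rs1799945 and rs855791 instrument
#' all four biomarkers. The `other_allele` column is synthetic fixture
#' metadata (chosen non-palindromic), not published data.
#'
#' @param biomarker One of `"ferritin"`, `"iron"`, `"transferrin"`,
#'   `"ts"`.
#' @return A summary-statistic tibble (see [read_summary_table()]).
#' @export
#' @examples
#' iron_hf_exposure("ferritin")
iron_hf_exposure <- function(biomarker = names(IRON_BIOMARKERS)) {
  biomarker <- match.arg(biomarker)
  read_summary_table(fixture_path(IRON_BIOMARKERS[[biomarker]]),
                     trait = biomarker)
}

#' Packaged outcome summary statistics: heart failure in UK Biobank
#'
#' SNP-heart-failure associations for the 12 iron-status instruments from
#' the Neale-lab UK Biobank analysis (n = 361,194; the source reports
#' both 1088/360,106 and 1405/359,789 cases/controls). Betas are
#' linear-model effects on the 0/1 trait. Allele and outcome-EAF columns
#' are synthetic fixture metadata.
#'
#' @return A summary-statistic tibble.
#' @export
iron_hf_outcome <- function() {
  read_summary_table(fixture_path("ukb_heart_failure.tsv"),
                     trait = "heart_failure")
}

#' Harmonised iron-status / heart-failure instrument sets
#'
#' The packaged biomarker exposures harmonised against the heart-failure
#' outcome: the analysis-ready version of the published instrument table.
#'
#' @param biomarker A single biomarker name, or `"all"` (default) for a
#'   named list with one harmonised tibble per biomarker.
#' @param ... Passed to [harmonise()].
#' @return A harmonised instrument tibble, or a named list of them.
#' @export
#' @examples
#' iron_hf_instruments("iron")
iron_hf_instruments <- function(biomarker = c("all", names(IRON_BIOMARKERS)),
                                ...) {
  biomarker <- match.arg(biomarker)
  one <- function(bm) {
    harmonise(iron_hf_exposure(bm), iron_hf_outcome(),
              exposure_name = bm, ...)
  }
  if (biomarker == "all") {
    sets <- lapply(names(IRON_BIOMARKERS), one)
    names(sets) <- names(IRON_BIOMARKERS)
    sets
  } else {
    one(biomarker)
  }
}

#' Wide instruments-by-biomarkers matrix for multivariable analyses
#'
#' The 12-instrument by 4-biomarker input for [mr_bma()] and
#' [mvmr_ivw()]: each biomarker column holds the SNP-exposure effects,
#' zero for SNPs that are not genome-wide-significant instruments of that
#' biomarker, alongside the shared heart-failure effect and SE.
#'
#' @return A tibble with columns `snp_id`, `ferritin`, `iron`,
#'   `transferrin`, `ts`, `beta_y`, `se_y`.
#' @export
#' @examples
#' iron_hf_matrix()
iron_hf_matrix <- function() {
  bma_input(iron_hf_instruments("all"))
}
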