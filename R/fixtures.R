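# Packaged reference fixtures: the published per-scenario score table, the
# dietary-risk factor table and the scenario compositions printed in the
# source study's results. These are verbatim data, checksum-verified on
# load; the package never claims to re-derive them from scratch.

.fixture_md5 <- c(
  "table1_scores.csv"        = "42c7e47d3d3eb904341b366d685620e8",
  "heni_factors.csv"         = "53d7833dc0ff3d79a687221c0f59c157",
  "printed_compositions.csv" = "59bdb3ca744173919e223ceefa5cae2e"
)

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "dietshift")
  if (!nzchar(p)) {
    # during development the package may be loaded from source
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) {
    stop_dietshift("CHECKSUM_MISMATCH", "packaged fixture %s not found", file)
  }
  p
}

.read_fixture <- function(file, verify = TRUE) {
  p <- .fixture_path(file)
  if (verify) {
    got <- unname(tools::md5sum(p))
    if (!identical(got, unname(.fixture_md5[file]))) {
      stop_dietshift("CHECKSUM_MISMATCH",
                     "fixture %s checksum %s != expected %s",
                     file, got, .fixture_md5[file])
    }
  }
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Published per-scenario nutrition score table
#'
#' The 24-scenario table of scaled Food Compass Scores and HENI minutes per
#' 100 kcal, as published. S1, S5 and S10 are shared across consumption
#' models and appear once each.
#'
#' @param verify Verify the packaged file's checksum (default `TRUE`).
#' @return Data frame: `scenario_id`, `scaled_fcs`, `heni_minutes`.
#' @export
table1_scores <- function(verify = TRUE) .read_fixture("table1_scores.csv", verify)

#' Dietary-risk HENI factor table
#'
#' The 15 Global-Burden-of-Disease dietary risks (9 food groups, 6
#' nutrients) and their DALY-scale HENI factors. Negative factors are
#' beneficial (seafood, the largest-magnitude, at -81.000); positive
#' factors are harmful. The published table omits intake units; the
#' `intake_unit` column declares the unit each factor is applied per
#' (grams throughout by default) and is data, not code, so corrected unit
#' sets drop in without code change.
#'
#' @param verify Verify the packaged file's checksum (default `TRUE`).
#' @return Data frame: `risk`, `factor`, `intake_unit`.
#' @export
heni_factors <- function(verify = TRUE) .read_fixture("heni_factors.csv", verify)

#' Printed targeted-group scenario compositions
#'
#' Percent-of-mass shares of the four targeted groups (legumes, processed,
#' red and white meat) for the ten scenarios whose compositions are printed
#' in the source study's results. The remaining intermediates' full
#' compositions were published only in a supplementary workbook and are
#' not packaged.
#'
#' @param verify Verify the packaged file's checksum (default `TRUE`).
#' @return Data frame: `scenario_id`, `legumes`, `processed_meat`,
#'   `red_meat`, `white_meat` (percent of 1800 g daily mass).
#' @export
printed_compositions <- function(verify = TRUE) {
  .read_fixture("printed_compositions.csv", verify)
}

#' Load all packaged fixtures
#'
#' @param verify Verify checksums (default `TRUE`).
#' @return List with `table1`, `heni_factors`, `printed_compositions`.
#' @export
load_fixtures <- function(verify = TRUE) {
  list(
    table1 = table1_scores(verify),
    heni_factors = heni_factors(verify),
    printed_compositions = printed_compositions(verify)
  )
}
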