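# Bundled pathway fixtures: six natural and six postulated CO2-fixation
# pathways, encoded against the published per-pathway aggregates (variant
# count, SLP cost, elementary reaction count, overall equation and its
# standard Gibbs energy).  Per-step dG0' values are standard-source
# estimates (pH 7, ionic strength 0.1 M) reconciled so that the elementary
# steps of every variant sum to the pathway's overall dG0'.

#' List the bundled pathway fixtures
#'
#' @return data.frame with the fixture id, name, oxygen class, end product
#'   and declared aggregates of each encoded pathway.
#' @export
list_pathway_fixtures <- function() {
  dir <- system.file("extdata", "pathways", package = "pathmdf")
  files <- sort(list.files(dir, pattern = "\\.json$"))
  rows <- lapply(files, function(f) {
    x <- jsonlite::fromJSON(file.path(dir, f), simplifyVector = FALSE)
    data.frame(id = x$id, name = x$name, oxygen_class = x$oxygen_class,
               end_product = x$end_product,
               slp_cost = x$declared$slp_cost,
               variants = x$declared$variants,
               reactions = x$declared$reactions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load a bundled pathway fixture
#'
#' @param id fixture id, e.g. `"rtca"`, `"dchb"`, `"hp4hb"`, `"hp_bicycle"`,
#'   `"wl_methanogenic"`, `"wl_acetogenic"`, `"via_pyruvate_ts"`,
#'   `"via_citrate_ts"`, `"via_malonyl_ts"`, `"via_malonyl_gs"`,
#'   `"cetch_ts"`, `"cetch_gs"`.
#' @return a validated `pmdf_pathway`.
#' @examples
#' p <- pathway_fixture("rtca")
#' length(enumerate_variants(p))  # 54
#' @export
pathway_fixture <- function(id) {
  path <- system.file("extdata", "pathways", paste0(id, ".json"),
                      package = "pathmdf")
  if (!nzchar(path)) {
    stop("no bundled pathway fixture named '", id, "'; see ",
         "list_pathway_fixtures()", call. = FALSE)
  }
  load_pathway(path)
}
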