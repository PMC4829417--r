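#' Packaged example tallies
#'
#' Two small packaged tables carrying the published field tallies of the
#' baboon patch experiments, with synthetic individual-level detail (the
#' identities and row order are constructed, the marginal counts are the
#' published ones):
#' `patchEntryEvents()` returns the 293 patch-entry (application) events
#' from the 44 experiments with extractable entry data, of which 14 were
#' co-feeds and 5 carried vocal protests (leaving 9 tolerated co-feeds);
#' `discoveryPositions()` returns the discoverer's spatial position for the
#' 50 experiments (28 leading edge, 11 side, 11 middle-back).
#'
#' @return A data.frame: entry events with `task_id`, `individual_id`,
#'   `fed`, `cofeed`, `protest`; or positions with `task_id`, `position`.
#' @examples
#' cofeedSummary(patchEntryEvents())     # 4.8% co-feeding, 3.1% tolerated
#' discoverySummary(discoveryPositions()$position)  # 56% leading edge
#' @export
patchEntryEvents <- function() {
  read.csv(system.file("extdata", "patch_entries_synthetic.csv",
                       package = "SocialDiffusion"),
           stringsAsFactors = FALSE)
}

#' @rdname patchEntryEvents
#' @export
discoveryPositions <- function() {
  read.csv(system.file("extdata", "discovery_positions_synthetic.csv",
                       package = "SocialDiffusion"),
           stringsAsFactors = FALSE)
}
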