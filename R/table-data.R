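#' Summary of simulated conditions
#'
#' Reads a per-condition table of trajectory counts and cumulative
#' simulation lengths (the bookkeeping of a multi-condition MD campaign)
#' and returns it together with the totals. The packaged default table
#' describes the four-condition dopamine-receptor campaign this pipeline
#' was designed around.
#'
#' @param path TSV with columns receptor, condition, n_trajectories,
#'   total_length_us; defaults to the packaged table.
#' @return list: `conditions` (data.frame), `total_trajectories`,
#'   `total_length_us`.
#' @export
condition_summary <- function(path = system.file("extdata",
                                                 "simulation_summary.tsv",
                                                 package = "posekin")) {
  tab <- utils::read.delim(path)
  stopifnot(all(c("n_trajectories", "total_length_us") %in% names(tab)))
  list(conditions = tab,
       total_trajectories = sum(tab$n_trajectories),
       total_length_us = sum(tab$total_length_us))
}
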