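## Ensemble bookkeeping for the five receptors analysed with the
## seed-clustering + clone-MD protocol.

#' Receptor study-design table with aggregate sampling times
#'
#' Loads the shipped per-receptor design table (starting structure, number
#' of metadynamics seed clusters, clone length) and recomputes each
#' receptor's aggregate sampling time as
#' n_seed_clusters x clone_length_ns / 1000 (microseconds).
#'
#' @return data.frame with columns `receptor`, `start_structure`,
#'   `n_seed_clusters`, `clone_length_ns`, `printed_aggregate_us` (NA where
#'   no aggregate is reported) and the recomputed `aggregate_us`.
#' @export
aggregate_sampling_table <- function() {
  path <- system.file("extdata", "study_design.csv", package = "tcrmsm",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$aggregate_us <- tab$n_seed_clusters * tab$clone_length_ns / 1000
  tab
}
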