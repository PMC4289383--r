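#' Pipeline parameters
#'
#' Bundle of the numeric thresholds used across the pipeline. Defaults are
#' the curation settings used throughout: RBH length-ratio window
#' \[0.5, 2.0\] (closed: exact boundary values are retained), two reverse
#' targets in the expansion screen, a 10-gene-spacer tandem window,
#' collinear chains of at least 5 pairs with a maximum chaining gap of 20
#' gene ranks, block merging across up to 350 gene spacers, a maximum block
#' mean Ks of 1.5 (lineage-specific duplication window), and the
#' NB-ARC-and-LRR domain requirement for family membership.
#'
#' @param length_ratio_min,length_ratio_max closed bounds on the
#'   query/subject sequence-length ratio for the filtered RBH channel
#' @param reverse_max_targets number of reverse-screen subjects kept per
#'   candidate (before self-hit removal)
#' @param tandem_spacer_window maximum number of intervening gene models
#'   between two tandem-array neighbours
#' @param chain_min_size minimum number of collinear pairs per synteny block
#' @param chain_max_gap maximum rank gap between consecutive chained pairs
#' @param block_merge_spacers maximum rank gap for merging adjacent blocks
#' @param block_ks_min,block_ks_max retained window for block mean Ks
#' @param synteny_min_score minimum raw hit score for a gene pair to enter
#'   collinearity chaining (the external-aligner analog feeds only
#'   significant hits into synteny detection; family screens remain
#'   unfiltered)
#' @param required_domains domain labels that must all be present for a gene
#'   to be scored a family member
#' @param min_predictors minimum number of distinct predictors that must
#'   report a domain before it counts as present (union rule: 1)
#' @return an object of class `pipeline_params`
#' @export
pipeline_params <- function(length_ratio_min = 0.5,
                            length_ratio_max = 2.0,
                            reverse_max_targets = 2L,
                            tandem_spacer_window = 10L,
                            chain_min_size = 5L,
                            chain_max_gap = 20L,
                            block_merge_spacers = 350L,
                            block_ks_min = 0,
                            block_ks_max = 1.5,
                            synteny_min_score = 100,
                            required_domains = c("NB-ARC", "LRR"),
                            min_predictors = 1L) {
  num <- c(length_ratio_min = length_ratio_min,
           length_ratio_max = length_ratio_max,
           reverse_max_targets = reverse_max_targets,
           tandem_spacer_window = tandem_spacer_window,
           chain_min_size = chain_min_size, chain_max_gap = chain_max_gap,
           block_merge_spacers = block_merge_spacers,
           block_ks_max = block_ks_max,
           synteny_min_score = synteny_min_score,
           min_predictors = min_predictors)
  if (any(num <= 0))
    stop("all thresholds must be strictly positive: ",
         paste(names(num)[num <= 0], collapse = ", "), call. = FALSE)
  if (block_ks_min < 0) stop("block_ks_min must be >= 0", call. = FALSE)
  if (length_ratio_min > length_ratio_max)
    stop("length_ratio_min exceeds length_ratio_max", call. = FALSE)
  structure(list(
    length_ratio_min = length_ratio_min,
    length_ratio_max = length_ratio_max,
    reverse_max_targets = as.integer(reverse_max_targets),
    tandem_spacer_window = as.integer(tandem_spacer_window),
    chain_min_size = as.integer(chain_min_size),
    chain_max_gap = as.integer(chain_max_gap),
    block_merge_spacers = as.integer(block_merge_spacers),
    block_ks_min = block_ks_min,
    block_ks_max = block_ks_max,
    synteny_min_score = synteny_min_score,
    required_domains = required_domains,
    min_predictors = as.integer(min_predictors)
  ), class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("pipeline_params:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
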