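# Shared fixtures: the default synthetic clade and one full pipeline run,
# generated once per test session and reused across files.
.fixture_env <- new.env(parent = emptyenv())

default_clade <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- generate_clade(clade_config(seed = 101L))
  .fixture_env$sim
}

default_report <- function() {
  if (is.null(.fixture_env$rep)) {
    sim <- default_clade()
    ref_fam <- sim$truth$gene_id[sim$truth$species == "sp1" &
                                   sim$truth$family]
    .fixture_env$rep <- run_pipeline(sim$annotations, "sp1", ref_fam,
                                     verbose = FALSE)
  }
  .fixture_env$rep
}

truth_family <- function(sim) sim$truth$gene_id[sim$truth$family]

truth_array_sets <- function(sim) {
  keep <- !is.na(sim$truth$array_id)
  unname(lapply(split(sim$truth$gene_id[keep], sim$truth$array_id[keep]),
                sort))
}

truth_ohnolog_pairs <- function(sim) {
  keep <- sim$truth$family & !is.na(sim$truth$ohnolog_partner) &
    sim$truth$gene_id < sim$truth$ohnolog_partner
  paste(sim$truth$gene_id[keep], sim$truth$ohnolog_partner[keep])
}

# Class pairs read off the ground truth (no homology search needed): the
# pairing rules of the rate analysis applied to planted labels.
truth_class_pairs <- function(sim) {
  tr <- sim$truth
  out <- list()
  for (aid in unique(tr$array_id[!is.na(tr$array_id)])) {
    m <- tr$gene_id[!is.na(tr$array_id) & tr$array_id == aid]
    out[[length(out) + 1L]] <- data.frame(
      species = tr$species[match(m[1], tr$gene_id)],
      gene_a = m[1], gene_b = m[length(m)], class = "tandem",
      stringsAsFactors = FALSE)
  }
  keep <- tr$family & !is.na(tr$ohnolog_partner) &
    tr$gene_id < tr$ohnolog_partner
  for (i in which(keep))
    out[[length(out) + 1L]] <- data.frame(
      species = tr$species[i], gene_a = tr$gene_id[i],
      gene_b = tr$ohnolog_partner[i], class = "ohnolog",
      stringsAsFactors = FALSE)
  sing <- tr[tr$family & !is.na(tr$class) & tr$class == "singleton", ]
  for (sp in unique(sing$species)) {
    s <- sing[sing$species == sp, ]
    for (loc in unique(s$locus)) {
      m <- sort(s$gene_id[s$locus == loc])
      if (length(m) == 2L)
        out[[length(out) + 1L]] <- data.frame(
          species = sp, gene_a = m[1], gene_b = m[2], class = "singleton",
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# NG86 rates for truth class pairs of one simulated clade.
truth_class_rates <- function(sim) {
  pairs <- truth_class_pairs(sim)
  pairs$omega <- vapply(seq_len(nrow(pairs)), function(i) {
    ann <- sim$annotations[[pairs$species[i]]]
    rates_for_pair(ann, pairs$gene_a[i], pairs$gene_b[i])$omega
  }, numeric(1))
  pairs
}
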