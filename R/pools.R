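#' Define the cross/pool design
#'
#' The design maps each sequenced pool (sample) to the status of each mutant
#' lineage in that pool. Per (sample, lineage) entry:
#' \describe{
#'   \item{`fixed`}{the pool was phenotype-selected for this lineage: its
#'     causative lesions are carried by every isolate; its background
#'     mutations segregate 1:1.}
#'   \item{`segregating`}{no selection on this lineage: causative and
#'     background mutations all segregate 1:1.}
#'   \item{`absent`}{the pool was selected for the wild-type allele: the
#'     causative lesions are carried by no isolate, but the lineage entered
#'     the cross, so its background mutations still segregate 1:1.}
#'   \item{`none`}{the lineage did not enter the cross for this pool;
#'     nothing from it is present.}
#' }
#'
#' @param samples character vector of pool (sample) ids.
#' @param lineages character vector of lineage labels.
#' @param presence character matrix `samples x lineages` with the entries
#'   above (dimnames optional; taken from `samples`/`lineages`).
#' @param n_isolates haploid single-spore isolates per pool (default 40).
#' @return object of class `pool_design`.
#' @export
pool_design <- function(samples, lineages, presence, n_isolates = 40L) {
  presence <- as.matrix(presence)
  if (!all(dim(presence) == c(length(samples), length(lineages))))
    ps_config_error("presence must be a samples x lineages matrix")
  dimnames(presence) <- list(samples, lineages)
  ok <- c("fixed", "segregating", "absent", "none")
  if (!all(presence %in% ok))
    ps_config_error("presence entries must be one of %s",
                    paste(ok, collapse = "/"))
  for (l in lineages) {
    if (!any(presence[, l] == "fixed"))
      ps_config_error("lineage '%s' is fixed in no sample; its expected pattern is empty", l)
  }
  structure(list(samples = samples, lineages = lineages,
                 presence = presence, n_isolates = as.integer(n_isolates)),
            class = "pool_design")
}

#' Expected penetrant-sample pattern of a lineage
#' @param design a [pool_design()].
#' @param lineage lineage label.
#' @return character vector of samples in which the lineage's causative
#'   lesions are fixed.
#' @export
expected_pattern <- function(design, lineage) {
  design$samples[design$presence[, lineage] == "fixed"]
}

#' Simulate the genotype composition of one pool
#'
#' Draws, for every mutation spec, the number of isolates in the pool that
#' carry it. Causative lesions are forced to `n_isolates` (fixed) or 0
#' (absent/none) by the phenotype selection; everything segregating is an
#' independent `Binomial(n_isolates, 0.5)` draw (unlinked loci; haploid
#' Mendelian 1:1).
#'
#' @param specs list of [mutation_spec()].
#' @param design a [pool_design()].
#' @param sample sample id, must be one of `design$samples`.
#' @param seed optional integer seed.
#' @return integer vector of isolate counts, one per spec, with attribute
#'   `genotypes`: an `n_isolates x length(specs)` logical carrier matrix.
#' @export
simulate_pool <- function(specs, design, sample, seed = NULL) {
  if (!inherits(design, "pool_design")) ps_input_error("design must be a pool_design")
  if (!sample %in% design$samples)
    ps_input_error("sample '%s' not in design", sample)
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_isolates
  counts <- integer(length(specs))
  geno <- matrix(FALSE, n, length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (!s$lineage %in% design$lineages)
      ps_input_error("spec lineage '%s' not in design", s$lineage)
    st <- design$presence[sample, s$lineage]
    k <- if (st == "none") 0L
    else if (s$causative) switch(st, fixed = n, absent = 0L,
                                 segregating = rbinom(1L, n, 0.5))
    else rbinom(1L, n, 0.5)
    counts[i] <- k
    if (k > 0L) geno[sample.int(n, k), i] <- TRUE
  }
  attr(counts, "genotypes") <- geno
  counts
}

#' Construct the isolate haplotype genomes of a pool
#'
#' @param genome reference genome.
#' @param specs list of mutation specs.
#' @param genotypes logical carrier matrix (`attr(simulate_pool(...), "genotypes")`).
#' @return list of mutant genomes, one per isolate.
#' @export
build_pool_haplotypes <- function(genome, specs, genotypes) {
  # validate once against the reference; per-isolate subsets reuse the result
  plant_mutations(genome, specs)
  lapply(seq_len(nrow(genotypes)), function(i) {
    carried <- specs[genotypes[i, ]]
    if (length(carried) == 0L) return(genome)
    apply_specs(genome, carried)
  })
}
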