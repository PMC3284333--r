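#' Describe a single planted mutation
#'
#' A mutation spec records one lesion in reference coordinates (0-based).
#' Kinds follow the lesion spectrum of EMS-mutagenised strains: point
#' mutations, indels of fewer than 4 bases, kilobase-scale deletions, and
#' balanced "complex replacements" in which the deleted interval is occupied
#' by duplicated (optionally inverted) copies of adjacent sequence.
#'
#' Conventions: `snp` substitutes the base at `pos`; `small_insertion`
#' inserts `alt` immediately *after* `pos`; deletions remove `len` bases
#' starting *at* `pos`. For `complex_replacement` the interval
#' `[pos, pos + len)` is deleted and replaced by the concatenation of the
#' `plan` segments, each a reference interval copied forward or
#' reverse-complemented.
#'
#' @param kind one of `snp`, `small_insertion`, `small_deletion`,
#'   `large_deletion`, `complex_replacement`.
#' @param contig contig name.
#' @param pos 0-based reference position (see conventions above).
#' @param ref reference allele (`snp`: the single base; deletions: the
#'   deleted string, may be omitted when `len` is given; insertions: `""`).
#' @param alt alternate allele (`snp`: single base; insertions: inserted
#'   string of 1-3 bases; deletions: `""`).
#' @param len deletion length in bases (deletions and complex replacements).
#' @param plan for `complex_replacement`: data.frame with columns `start`,
#'   `end` (0-based half-open reference intervals) and `orientation`
#'   (`"fwd"` or `"rev"`).
#' @param lineage label of the mutant line carrying the lesion.
#' @param causative logical; is this the phenotype-causing lesion?
#' @return an object of class `mutation_spec`.
#' @export
mutation_spec <- function(kind, contig, pos, ref = "", alt = "", len = NULL,
                          plan = NULL, lineage = "", causative = FALSE) {
  kinds <- c("snp", "small_insertion", "small_deletion", "large_deletion",
             "complex_replacement")
  if (!kind %in% kinds) ps_input_error("unknown mutation kind '%s'", kind)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 0L) ps_input_error("pos must be a non-negative integer")
  if (kind == "snp") {
    if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt)
      ps_input_error("snp needs single differing ref/alt bases")
    len <- 1L
  } else if (kind == "small_insertion") {
    if (nchar(alt) < 1L || nchar(alt) > 3L)
      ps_input_error("small insertions are 1-3 bases")
    ref <- ""
    len <- 0L
  } else if (kind == "small_deletion") {
    if (is.null(len)) len <- nchar(ref)
    if (len < 1L || len > 3L) ps_input_error("small deletions are 1-3 bases")
    alt <- ""
  } else if (kind == "large_deletion") {
    if (is.null(len)) len <- nchar(ref)
    if (len < 500L)
      ps_input_error("large deletions are >= 500 b; use small_deletion below 4 b")
    alt <- ""
  } else if (kind == "complex_replacement") {
    if (is.null(len) || len < 500L)
      ps_input_error("complex replacements delete >= 500 b")
    if (is.null(plan) || !all(c("start", "end", "orientation") %in% names(plan)))
      ps_input_error("complex_replacement needs a plan with start/end/orientation")
    if (!all(plan$orientation %in% c("fwd", "rev")))
      ps_input_error("plan orientation must be 'fwd' or 'rev'")
  }
  structure(list(kind = kind, contig = contig, pos = pos, ref = ref,
                 alt = alt, len = as.integer(len), plan = plan,
                 lineage = lineage, causative = isTRUE(causative)),
            class = "mutation_spec")
}

# reference footprint [start, end) of a spec, for overlap checks
spec_footprint <- function(s) {
  if (s$kind == "small_insertion") c(s$pos, s$pos + 1L) else c(s$pos, s$pos + s$len)
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

#' Draw an EMS-style set of background mutations
#'
#' Generates `n` non-overlapping mutation specs for one lineage with the
#' transition-biased substitution spectrum typical of EMS mutagenesis, plus a
#' configurable fraction of sub-4-base indels.
#'
#' @param genome reference genome.
#' @param n number of mutations.
#' @param lineage lineage label.
#' @param ti_fraction fraction of SNPs that are transitions (default 0.9).
#' @param indel_fraction fraction of mutations that are 1-3 b indels
#'   (half insertions, half deletions).
#' @param min_spacing minimum distance in bases between drawn positions.
#' @param seed optional integer seed.
#' @return list of `mutation_spec`.
#' @export
random_mutation_specs <- function(genome, n, lineage, ti_fraction = 0.9,
                                  indel_fraction = 0.1, min_spacing = 10L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_genome(genome, allow_n = FALSE)
  lens <- nchar(genome)
  bases <- c("A", "C", "G", "T")
  specs <- vector("list", n)
  taken_pos <- numeric(0)
  taken_contig <- character(0)
  for (i in seq_len(n)) {
    repeat {
      ci <- sample.int(length(genome), 1L, prob = lens)
      p <- sample.int(lens[ci] - 10L, 1L) + 2L  # keep clear of contig edges
      same <- taken_contig == names(genome)[ci]
      if (!any(same) || all(abs(taken_pos[same] - p) >= min_spacing)) break
    }
    taken_pos <- c(taken_pos, p)
    taken_contig <- c(taken_contig, names(genome)[ci])
    contig <- names(genome)[ci]
    refb <- sub0(genome[[ci]], p, p + 1L)
    if (stats::runif(1) < indel_fraction) {
      ilen <- sample.int(3L, 1L)
      if (stats::runif(1) < 0.5) {
        specs[[i]] <- mutation_spec("small_insertion", contig, p,
                                    alt = paste(sample(bases, ilen, TRUE), collapse = ""),
                                    lineage = lineage)
      } else {
        specs[[i]] <- mutation_spec("small_deletion", contig, p,
                                    ref = sub0(genome[[ci]], p, p + ilen),
                                    len = ilen, lineage = lineage)
      }
    } else {
      altb <- if (stats::runif(1) < ti_fraction) transition_of[[refb]] else
        sample(setdiff(bases, c(refb, transition_of[[refb]])), 1L)
      specs[[i]] <- mutation_spec("snp", contig, p, ref = refb, alt = altb,
                                  lineage = lineage)
    }
  }
  specs
}

#' Apply mutation specs to a reference genome
#'
#' Mutations are validated against the reference (ref alleles must match,
#' footprints must not overlap) and applied in descending coordinate order,
#' so every spec's `pos` refers to the unmodified reference. For complex
#' replacements the deleted interval is substituted by the concatenated plan
#' segments, reverse-complemented where the orientation is `rev`.
#'
#' @param genome reference genome (named character vector).
#' @param specs list of [mutation_spec()] objects.
#' @return list with elements `genome` (the mutant genome), `truth`
#'   (data.frame of planted records in reference coordinates) and `specs`.
#' @export
plant_mutations <- function(genome, specs) {
  validate_genome(genome)
  if (inherits(specs, "mutation_spec")) specs <- list(specs)
  for (s in specs) {
    if (!s$contig %in% names(genome))
      ps_input_error("spec contig '%s' not in genome", s$contig)
    fp <- spec_footprint(s)
    if (fp[2] > nchar(genome[[s$contig]]))
      ps_input_error("spec at %s:%d extends beyond contig end", s$contig, s$pos)
    want <- switch(s$kind,
                   snp = s$ref,
                   small_insertion = "",
                   sub0(genome[[s$contig]], s$pos, s$pos + nchar(s$ref)))
    if (nchar(want) > 0 &&
        sub0(genome[[s$contig]], s$pos, s$pos + nchar(want)) != want)
      ps_consistency_error("ref allele mismatch for %s at %s:%d",
                           s$kind, s$contig, s$pos)
  }
  # overlap check per contig
  fps <- t(vapply(specs, spec_footprint, numeric(2)))
  ctg <- vapply(specs, function(s) s$contig, character(1))
  for (cc in unique(ctg)) {
    sel <- which(ctg == cc)
    o <- sel[order(fps[sel, 1])]
    if (length(o) > 1L && any(fps[o[-length(o)], 2] > fps[o[-1], 1]))
      ps_input_error("overlapping mutation specs on %s", cc)
  }

  mutant <- apply_specs(genome, specs)
  truth <- truth_table(specs)
  list(genome = mutant, truth = truth, specs = specs)
}

# Apply pre-validated specs: single-pass per contig. Splits the contig at
# every spec footprint and reassembles with one paste per contig.
apply_specs <- function(genome, specs) {
  mutant <- unclass(genome)
  if (length(specs) == 0L) {
    class(mutant) <- "ref_genome"
    return(mutant)
  }
  fps <- t(vapply(specs, spec_footprint, numeric(2)))
  ctg <- vapply(specs, function(s) s$contig, character(1))
  for (cc in unique(ctg)) {
    sel <- which(ctg == cc)
    sel <- sel[order(fps[sel, 1])]
    seq <- mutant[[cc]]
    pieces <- character(2L * length(sel) + 1L)
    prev_end <- 0L
    for (j in seq_along(sel)) {
      s <- specs[[sel[j]]]
      repl <- switch(s$kind,
        snp = s$alt,
        small_insertion = paste0(sub0(genome[[s$contig]], s$pos, s$pos + 1L), s$alt),
        small_deletion = "",
        large_deletion = "",
        complex_replacement = paste(
          mapply(function(a, b, o) {
            piece <- sub0(genome[[s$contig]], a, b)
            if (o == "rev") revcomp_chr(piece) else piece
          }, s$plan$start, s$plan$end, s$plan$orientation),
          collapse = ""))
      span <- if (s$kind == "small_insertion") c(s$pos, s$pos + 1L) else
        c(s$pos, s$pos + s$len)
      pieces[2L * j - 1L] <- substr(seq, prev_end + 1L, span[1])
      pieces[2L * j] <- repl
      prev_end <- span[2]
    }
    pieces[2L * length(sel) + 1L] <- substr(seq, prev_end + 1L, nchar(seq))
    mutant[[cc]] <- paste(pieces, collapse = "")
  }
  class(mutant) <- "ref_genome"
  mutant
}

#' Truth table of planted mutations
#' @param specs list of mutation specs.
#' @return data.frame with one row per spec, reference coordinates.
#' @export
truth_table <- function(specs) {
  data.frame(
    contig = vapply(specs, `[[`, character(1), "contig"),
    pos = vapply(specs, `[[`, integer(1), "pos"),
    kind = vapply(specs, `[[`, character(1), "kind"),
    ref = vapply(specs, `[[`, character(1), "ref"),
    alt = vapply(specs, `[[`, character(1), "alt"),
    len = vapply(specs, `[[`, integer(1), "len"),
    lineage = vapply(specs, `[[`, character(1), "lineage"),
    causative = vapply(specs, `[[`, logical(1), "causative"),
    stringsAsFactors = FALSE)
}
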