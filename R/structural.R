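#' Find sample-specific uncovered regions (putative deletions)
#'
#' Scans one sample's coverage track for maximal zero-depth runs of at least
#' `min_len` bases that are well covered in every other sample — the
#' signature of a homozygous deletion in that pool. Regions uncovered in all
#' samples are unsequenceable, not deletions, and are not reported.
#' Zero-runs separated by fewer than `gap_join` covered bases are merged
#' before the length test.
#'
#' @param tracks named list of coverage tracks (one per sample; see
#'   [coverage_track()]).
#' @param target sample to scan for gaps.
#' @param min_len minimum event length in bases (default 500).
#' @param other_min_depth minimum mean depth required of every other sample
#'   over the run (default 5).
#' @param gap_join merge zero-runs separated by fewer than this many bases
#'   (default 50).
#' @return data.frame of structural candidates: `contig`, `start`, `end`
#'   (0-based half-open), `length`, `evidence = "coverage_gap"`,
#'   `target_sample`, and mean in-interval depth per sample
#'   (`depth_<s>` columns).
#' @export
find_uncovered_regions <- function(tracks, target, min_len = 500L,
                                   other_min_depth = 5, gap_join = 50L) {
  if (!target %in% names(tracks))
    ps_input_error("target sample '%s' not in tracks", target)
  others <- setdiff(names(tracks), target)
  contigs <- names(tracks[[target]])
  for (s in names(tracks)) {
    if (!identical(names(tracks[[s]]), contigs) ||
        !identical(lengths(tracks[[s]]), lengths(tracks[[target]])))
      ps_consistency_error("coverage tracks are on different references")
  }
  out <- list()
  for (cc in contigs) {
    d <- tracks[[target]][[cc]]
    r <- rle(d == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths            # 0-based starts
    zs <- starts[r$values]; ze <- ends[r$values]
    if (length(zs) == 0L) next
    # merge zero-runs separated by < gap_join covered bases
    ms <- zs[1]; me <- ze[1]; merged <- list()
    if (length(zs) > 1L) {
      for (i in 2:length(zs)) {
        if (zs[i] - me < gap_join) me <- ze[i]
        else { merged[[length(merged) + 1L]] <- c(ms, me); ms <- zs[i]; me <- ze[i] }
      }
    }
    merged[[length(merged) + 1L]] <- c(ms, me)
    for (iv in merged) {
      if (iv[2] - iv[1] < min_len) next
      span <- (iv[1] + 1L):iv[2]
      omean <- vapply(others, function(s) mean(tracks[[s]][[cc]][span]),
                      numeric(1))
      if (length(others) == 0L || any(omean < other_min_depth)) next
      row <- data.frame(contig = cc, start = iv[1], end = iv[2],
                        length = iv[2] - iv[1], evidence = "coverage_gap",
                        target_sample = target, stringsAsFactors = FALSE)
      row[[paste0("depth_", target)]] <- 0
      for (s in others) row[[paste0("depth_", s)]] <- round(omean[[s]], 1)
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) {
    cols <- c("contig", "start", "end", "length", "evidence", "target_sample",
              paste0("depth_", c(target, others)))
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  }
  do.call(rbind, out)
}

#' Detect mate-pair insert-size anomalies
#'
#' Bins properly paired alignments by the leftmost mate coordinate into
#' genomic windows roughly one library insert wide and reports windows of
#' at least `window` pairs whose median observed insert (outer distance)
#' deviates from the expected library insert by more than `z_threshold`
#' standard errors (`expected_sd / sqrt(n pairs)`). The median is used for
#' robustness to chimeric pairs, and pairs whose mates map to the same
#' strand are discarded first (improper orientation: inverted duplications,
#' chimeras). A deletion in the sequenced strain lengthens the observed
#' inserts of essentially every pair starting within one insert upstream of
#' it, so the window median shifts by about the deleted length; an
#' insertion of novel sequence shortens inserts the same way (negative
#' deviation). A balanced replacement — deleted sequence substituted by
#' duplicated copies of the immediate flanks — scatters the mates landing
#' in the copies into a minority of short and long apparent inserts inside
#' an insert-sized window, so its window medians stay near the expectation
#' and no call is made: this detector and [find_uncovered_regions()] are
#' complementary.
#'
#' @param alignments alignment data.frame of one sample (needs `insert`;
#'   uses `strand`/`mate_strand` for the orientation filter when present).
#' @param expected_insert expected library insert in bases (default 2000).
#' @param expected_sd library insert standard deviation (default 200).
#' @param window minimum pairs per evaluated window (default 50).
#' @param z_threshold deviation threshold in standard-error units
#'   (default 6).
#' @param bin_width genomic window width in bases (default
#'   `expected_insert`).
#' @param min_shift minimum absolute median shift in bases (default
#'   `2.5 * expected_sd`): the screen targets kilobase-scale lesions, and a
#'   median shift smaller than a few library standard deviations is both
#'   below the detector's meaningful event size (compare `min_len` in the
#'   gap scan) and within the range that duplication-edge artifacts
#'   produce.
#' @return data.frame of candidates: `contig`, `start`, `end`,
#'   `evidence = "insert_anomaly"`, `target_sample`, `n_pairs`,
#'   `median_insert`, `expected_insert`, `deviation` (bases) and `z`
#'   (deviation score). Adjacent flagged windows are merged.
#' @export
insert_size_anomalies <- function(alignments, expected_insert = 2000,
                                  expected_sd = 200, window = 50L,
                                  z_threshold = 6, bin_width = NULL,
                                  min_shift = NULL) {
  if (is.null(bin_width)) bin_width <- expected_insert
  if (is.null(min_shift)) min_shift <- 2.5 * expected_sd
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), evidence = character(0),
                      target_sample = character(0), n_pairs = integer(0),
                      median_insert = numeric(0), expected_insert = numeric(0),
                      deviation = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE)
  pairs <- alignments[!is.na(alignments$insert) &
                        alignments$pos <= alignments$mate_pos, , drop = FALSE]
  if ("mate_strand" %in% names(pairs)) {
    ok <- is.na(pairs$mate_strand) | pairs$strand != pairs$mate_strand
    pairs <- pairs[ok, , drop = FALSE]
  }
  # for pairs at identical positions keep one record per read id
  pairs <- pairs[!duplicated(pairs$read_id), , drop = FALSE]
  if (nrow(pairs) == 0L) {
    warning("no paired alignments with observed inserts")
    return(empty)
  }
  sample_id <- pairs$sample_id[1]
  out <- list()
  for (cc in unique(pairs$contig)) {
    p <- pairs[pairs$contig == cc, , drop = FALSE]
    p <- p[order(p$pos), , drop = FALSE]
    bin <- p$pos %/% bin_width
    flagged <- NULL
    for (b in unique(bin)) {
      i <- which(bin == b)
      if (length(i) < window) next
      med <- median(p$insert[i])
      dev <- med - expected_insert
      se <- expected_sd / sqrt(length(i))
      if (abs(dev) > z_threshold * se && abs(dev) >= min_shift) {
        rec <- c(bin = b, start = min(p$pos[i]),
                 end = max(p$pos[i] + p$insert[i]),
                 n = length(i), med = med, dev = dev, z = dev / se)
        flagged <- rbind(flagged, rec)
      }
    }
    if (is.null(flagged)) next
    flagged <- flagged[order(flagged[, "bin"]), , drop = FALSE]
    # merge adjacent flagged windows
    merged <- list(flagged[1, ])
    if (nrow(flagged) > 1L) {
      for (j in 2:nrow(flagged)) {
        last <- merged[[length(merged)]]
        if (flagged[j, "bin"] <= last["bin"] + 1) {
          # keep the most extreme bin's statistics for the merged call
          if (abs(flagged[j, "dev"]) > abs(last["dev"])) {
            last["med"] <- flagged[j, "med"]
            last["dev"] <- flagged[j, "dev"]
          }
          last["bin"] <- flagged[j, "bin"]
          last["end"] <- max(last["end"], flagged[j, "end"])
          last["n"] <- last["n"] + flagged[j, "n"]
          last["z"] <- max(abs(last["z"]), abs(flagged[j, "z"])) *
            sign(last["dev"])
          merged[[length(merged)]] <- last
        } else merged[[length(merged) + 1L]] <- flagged[j, ]
      }
    }
    for (m in merged) {
      out[[length(out) + 1L]] <- data.frame(
        contig = cc, start = unname(m["start"]), end = unname(m["end"]),
        evidence = "insert_anomaly", target_sample = sample_id,
        n_pairs = unname(m["n"]), median_insert = unname(m["med"]),
        expected_insert = expected_insert, deviation = unname(m["dev"]),
        z = unname(m["z"]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Write structural candidates as BED (0-based half-open)
#' @param candidates data.frame from [find_uncovered_regions()] or
#'   [insert_size_anomalies()].
#' @param path output file.
#' @export
write_bed <- function(candidates, path) {
  if (nrow(candidates) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- sprintf("%s|%s", candidates$evidence, candidates$target_sample)
  extra <- setdiff(names(candidates), c("contig", "start", "end"))
  bed <- cbind(candidates[, c("contig", "start", "end")], name,
               candidates[, setdiff(extra, c("evidence", "target_sample")),
                          drop = FALSE])
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export a coverage track as bedGraph
#' @param track coverage track of one sample ([coverage_track()]).
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cc in names(track)) {
    r <- rle(as.integer(track[[cc]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", cc, starts, ends, r$values), con)
  }
  invisible(path)
}
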