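#' Read and validate a pipeline configuration
#'
#' Configurations are flat YAML with a `mode` (`simulate` or `real`), a
#' `seed` (mandatory in simulate mode), and optional `simulate`, `screen`
#' and `structural` blocks overriding stage defaults. Real mode requires a
#' `real` block naming the reference FASTA, the pool design, and per-sample
#' inputs (SAM files, or FASTQ mates to map internally); referenced files
#' must exist.
#'
#' @param path YAML file.
#' @return object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) ps_config_error("config file '%s' not found", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) ps_config_error("bad YAML: %s",
                                                      conditionMessage(e)))
  cfg$config_path <- path
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$mode) || !cfg$mode %in% c("simulate", "real"))
    ps_config_error("mode must be 'simulate' or 'real'")
  if (cfg$mode == "simulate" && is.null(cfg$seed))
    ps_config_error("simulate mode requires a seed")
  if (cfg$mode == "real") {
    r <- cfg$real
    if (is.null(r$reference) || !file.exists(r$reference))
      ps_config_error("real mode: reference FASTA missing")
    if (!is.null(r$gff) && !file.exists(r$gff))
      ps_config_error("real mode: gff '%s' not found", r$gff)
    if (is.null(r$design) || is.null(r$samples))
      ps_config_error("real mode: design and samples required")
    for (s in r$samples) {
      for (f in c(s$sam, s$fastq1, s$fastq2))
        if (!is.null(f) && !file.exists(f))
          ps_config_error("real mode: input '%s' not found", f)
    }
  }
  structure(cfg, class = "pipeline_config")
}

cfg_get <- function(cfg, block, key, default) {
  v <- cfg[[block]][[key]]
  if (is.null(v)) default else v
}

screen_config_from <- function(cfg) {
  screen_config(
    coverage_fraction = cfg_get(cfg, "screen", "coverage_fraction", 0.4),
    penetrance_min = cfg_get(cfg, "screen", "penetrance_min", 1.0),
    absence_max_alt = cfg_get(cfg, "screen", "absence_max_alt", 0L),
    min_absent_depth = cfg_get(cfg, "screen", "min_absent_depth", 1L),
    homopolymer_min_run = cfg_get(cfg, "screen", "homopolymer_min_run", 3L),
    strict_all_samples = cfg_get(cfg, "screen", "strict_all_samples", FALSE))
}

stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e) {
    cls <- class(e)[1]
    ps_abort(if (grepl("^ps_", cls)) cls else "ps_error",
             "stage %s failed: %s", name, conditionMessage(e))
  })
}

#' Run the pooled-sequencing pipeline end to end
#'
#' Executes simulate (optional) -> clean -> map -> pileup -> small-variant
#' screen -> structural screen -> annotate -> report from a single
#' configuration, writing all artifact files under `outdir` and logging each
#' stage with its read/variant counts. Reruns with the same config and seed
#' are reproducible.
#'
#' @param config a [read_pipeline_config()] result, a path to one, or an
#'   equivalent list.
#' @param outdir output directory (created if needed).
#' @param quiet suppress console logging (the log file is always written).
#' @return a `ps_run_report` (invisibly also written under `outdir`).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  cat("", file = logfile)
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    cat(line, "\n", file = logfile, append = TRUE)
    if (!quiet) message(line)
  }
  scfg <- screen_config_from(config)

  if (config$mode == "simulate") {
    set.seed(config$seed)
    sim <- config$simulate
    scen <- stage("simulate", log, {
      sc <- study_scenario(
        genome_length = cfg_get(config, "simulate", "genome_length", 2e6),
        n_contigs = cfg_get(config, "simulate", "n_contigs", 1L),
        gc = cfg_get(config, "simulate", "gc", 0.5),
        n_background = cfg_get(config, "simulate", "n_background", 40L),
        n_isolates = cfg_get(config, "simulate", "n_isolates", 40L))
      write_genome_fasta(sc$genome, file.path(outdir, "reference.fasta"))
      write_gene_models_gff(sc$models, file.path(outdir, "genes.gff3"))
      log(sprintf("simulated genome %d b, %d mutation specs, %d samples",
                  genome_length(sc$genome), length(sc$specs),
                  length(sc$design$samples)))
      sc
    })
    genome <- scen$genome
    models <- scen$models
    design <- scen$design
    read_len <- cfg_get(config, "simulate", "read_len", 76L)
    coverage <- cfg_get(config, "simulate", "coverage", 50)

    pileups <- list()
    alns <- list()
    summary <- NULL
    truth <- scen$truth
    for (s in design$samples) {
      sim_s <- stage(paste0("simulate:", s), log, {
        r <- simulate_sample_reads(
          scen, s, coverage, read_len,
          insert_mean = cfg_get(config, "simulate", "insert_mean", 2000),
          insert_sd = cfg_get(config, "simulate", "insert_sd", 200),
          error_rate = cfg_get(config, "simulate", "error_rate", 0.005),
          n_rate = cfg_get(config, "simulate", "n_rate", 0.001))
        write_fastq(r$reads$mate1, file.path(outdir, sprintf("%s_raw_1.fastq", s)))
        write_fastq(r$reads$mate2, file.path(outdir, sprintf("%s_raw_2.fastq", s)))
        truth[[paste0("isolates_", s)]] <- as.integer(r$pool)
        log(sprintf("%s: %d fragments simulated", s, n_reads(r$reads$mate1)))
        r
      })
      cl <- stage(paste0("clean:", s), log, {
        x <- clean_reads(sim_s$reads$mate1, sim_s$reads$mate2,
                         out_prefix = file.path(outdir, paste0(s, "_clean")))
        log(sprintf("%s: cleaned %d -> %d pairs + %d singles (%d dropped)",
                    s, x$counts[["input_reads"]] / 2, x$counts[["retained_pairs"]],
                    x$counts[["singles"]], x$counts[["dropped"]]))
        x
      })
      rm(sim_s)
      aln <- stage(paste0("map:", s), log, {
        a <- map_reads(cl, genome, sample_id = s)
        cnt <- attr(a, "counts")
        log(sprintf("%s: mapped %d/%d reads (%.1f%%)", s, cnt[["n_mapped"]],
                    cnt[["n_input"]], 100 * cnt[["n_mapped"]] / cnt[["n_input"]]))
        a
      })
      rm(cl)
      cnt <- attr(aln, "counts")
      summary <- rbind(summary, sequencing_summary(
        cnt[["n_input"]], read_len, cnt[["n_mapped"]], genome_length(genome),
        sample_id = s))
      pileups[[s]] <- stage(paste0("pileup:", s), log, build_pileup(aln, genome))
      alns[[s]] <- aln[, c("read_id", "sample_id", "contig", "pos", "length",
                           "strand", "mate_strand", "mate_pos", "insert")]
      rm(aln)
    }
    write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    r <- config$real
    genome <- read_genome_fasta(r$reference)
    models <- if (!is.null(r$gff)) load_gene_models(r$gff) else list()
    d <- r$design
    pres <- do.call(rbind, lapply(d$samples, function(s)
      unlist(d$presence[[s]])[d$lineages]))
    design <- pool_design(d$samples, d$lineages, pres,
                          n_isolates = if (is.null(d$n_isolates)) 40L else d$n_isolates)
    read_len <- NA_integer_
    pileups <- list()
    alns <- list()
    summary <- NULL
    for (s in r$samples) {
      sid <- s$id
      aln <- if (!is.null(s$sam)) {
        stage(paste0("import:", sid), log, import_sam(s$sam, sample_id = sid))
      } else {
        cl <- stage(paste0("clean:", sid), log,
                    clean_reads(s$fastq1, s$fastq2))
        stage(paste0("map:", sid), log, map_reads(cl, genome, sample_id = sid))
      }
      n_in <- if (!is.null(attr(aln, "counts")))
        attr(aln, "counts")[["n_input"]] else nrow(aln)
      rl <- if (nrow(aln) > 0L) as.integer(round(mean(aln$length))) else 0L
      summary <- rbind(summary, sequencing_summary(
        n_in, rl, nrow(aln), genome_length(genome), sample_id = sid))
      pileups[[sid]] <- stage(paste0("pileup:", sid), log,
                              build_pileup(aln, genome))
      alns[[sid]] <- aln[, c("read_id", "sample_id", "contig", "pos", "length",
                             "strand", "mate_strand", "mate_pos", "insert")]
      rm(aln)
    }
  }

  mean_cov <- vapply(pileups, mean_coverage, numeric(1))
  screen <- stage("screen", log, {
    calls <- call_small_variants(pileups, genome, scfg)
    calls <- apply_coverage_filter(calls, mean_cov, scfg)
    sc <- screen_patterns(calls, design, scfg)
    sc <- flag_homopolymers(sc, genome, scfg)
    log(sprintf("screen: %d sites; %s", nrow(sc),
                paste(sprintf("%s=%d", names(table(sc$classification)),
                              table(sc$classification)), collapse = " ")))
    write_screen_vcf(sc, genome, file.path(outdir, "variants.vcf"))
    sc
  })

  structural <- stage("structural", log, {
    tracks <- lapply(pileups, coverage_track)
    gaps <- list()
    for (s in names(tracks)) {
      g <- find_uncovered_regions(
        tracks, s,
        min_len = cfg_get(config, "structural", "min_len", 500L),
        other_min_depth = cfg_get(config, "structural", "other_min_depth", 5),
        gap_join = cfg_get(config, "structural", "gap_join", 50L))
      an <- insert_size_anomalies(
        alns[[s]],
        expected_insert = cfg_get(config, "simulate", "insert_mean", 2000),
        expected_sd = cfg_get(config, "simulate", "insert_sd", 200),
        window = cfg_get(config, "structural", "window", 50L),
        z_threshold = cfg_get(config, "structural", "z_threshold", 6))
      common <- c("contig", "start", "end", "evidence", "target_sample")
      if (nrow(g) > 0L) gaps[[length(gaps) + 1L]] <- g[, common]
      if (nrow(an) > 0L) gaps[[length(gaps) + 1L]] <- an[, common]
      write_bedgraph(tracks[[s]], file.path(outdir, sprintf("%s_coverage.bedgraph", s)))
    }
    out <- if (length(gaps) > 0L) do.call(rbind, gaps) else
      data.frame(contig = character(0), start = integer(0), end = integer(0),
                 evidence = character(0), target_sample = character(0))
    log(sprintf("structural: %d candidate(s)", nrow(out)))
    write_bed(out, file.path(outdir, "structural.bed"))
    out
  })

  consequences <- stage("annotate", log, {
    ann <- annotate_candidates(screen, models, genome)
    if (nrow(ann) > 0L)
      write.table(ann, file.path(outdir, "consequences.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    ann
  })

  report <- structure(list(
    summary = summary,
    screen_summary = screen_summary(screen, design),
    pattern_candidates = screen[screen$classification == "pattern_candidate", ,
                                drop = FALSE],
    structural = structural,
    consequences = consequences,
    counts = table(screen$classification),
    provenance = list(
      seed = config$seed,
      config_hash = if (!is.null(config$config_path))
        unname(tools::md5sum(config$config_path)) else NA_character_,
      package_version = as.character(utils::packageVersion("poolscreen")))),
    class = "ps_run_report")
  render_tables(report, outdir)
  log("pipeline complete")
  invisible(report)
}

#' Annotate pattern candidates with molecular consequences
#'
#' @param screen a `ps_screen`.
#' @param models gene models.
#' @param genome reference genome.
#' @return data.frame with one row per pattern candidate.
#' @export
annotate_candidates <- function(screen, models, genome) {
  pc <- screen[screen$classification == "pattern_candidate", , drop = FALSE]
  if (nrow(pc) == 0L || length(models) == 0L) {
    if (nrow(pc) == 0L)
      return(data.frame(contig = character(0), pos = integer(0),
                        lineage = character(0), category = character(0),
                        gene_id = character(0), detail = character(0)))
  }
  rows <- lapply(seq_len(nrow(pc)), function(i) {
    v <- list(contig = pc$contig[i], pos = pc$pos[i], type = pc$type[i],
              ref = pc$ref[i], alt = pc$alt[i], len = nchar(pc$ref[i]))
    cons <- classify_variant(v, models, genome)
    detail <- cons$detail
    if (cons$category == "stop_loss") {
      mut <- plant_mutations(genome, mutation_spec("snp", v$contig, v$pos,
                                                   ref = v$ref, alt = v$alt))
      ext <- stop_loss_extension(models[[cons$gene_id]], mut$genome)
      detail <- sprintf("%s; %d aa C-terminal extension", detail,
                        ext$extension_aa)
    } else if (cons$category == "splice_donor") {
      ii <- as.integer(sub("^intron (\\d+).*$", "\\1", cons$detail))
      tr <- splice_defect_transcripts(models[[cons$gene_id]], genome, ii)
      detail <- sprintf("%s; retention peptide %d aa (wild type %d aa)",
                        detail, tr$peptide_len[tr$transcript == "retention"],
                        tr$peptide_len[tr$transcript == "wild_type"])
    }
    data.frame(contig = pc$contig[i], pos = pc$pos[i],
               lineage = pc$matched_lineage[i], category = cons$category,
               gene_id = ifelse(is.na(cons$gene_id), ".", cons$gene_id),
               detail = detail, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render run-report tables
#'
#' Writes the per-sample sequencing summary, the per-genotype variant
#' summary, structural candidates and consequences as TSV plus a
#' human-readable `report.txt`.
#'
#' @param report a `ps_run_report`.
#' @param outdir output directory.
#' @export
render_tables <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$summary, file.path(outdir, "table_sequencing.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$screen_summary, file.path(outdir, "table_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- file.path(outdir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines("== Sequencing summary ==", con)
  writeLines(capture_df(report$summary), con)
  writeLines("", con)
  writeLines("== Small-variant screen (per genotype) ==", con)
  writeLines(capture_df(report$screen_summary), con)
  writeLines("", con)
  writeLines("== Pattern candidates ==", con)
  pc <- report$pattern_candidates
  if (nrow(pc) > 0L)
    writeLines(capture_df(pc[, c("contig", "pos", "type", "ref", "alt",
                                 "pattern", "matched_lineage")]), con)
  writeLines("", con)
  writeLines("== Structural candidates ==", con)
  if (nrow(report$structural) > 0L)
    writeLines(capture_df(report$structural), con)
  writeLines("", con)
  writeLines("== Consequences ==", con)
  if (nrow(report$consequences) > 0L)
    writeLines(capture_df(report$consequences), con)
  writeLines("", con)
  writeLines(sprintf("seed: %s  config: %s  poolscreen %s",
                     report$provenance$seed, report$provenance$config_hash,
                     report$provenance$package_version), con)
  invisible(outdir)
}

capture_df <- function(df) utils::capture.output(print(df, row.names = FALSE))

#' @export
print.ps_run_report <- function(x, ...) {
  cat("pooled-sequencing run report\n\n")
  print(x$summary, row.names = FALSE)
  cat("\n")
  print(x$screen_summary, row.names = FALSE)
  cat("\nclassifications:\n")
  print(x$counts)
  if (nrow(x$consequences) > 0L) {
    cat("\nconsequences:\n")
    print(x$consequences, row.names = FALSE)
  }
  invisible(x)
}
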