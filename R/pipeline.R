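# One-command pipeline: alignment -> conservation banding -> GEnt tables
# -> motifs -> bootstrapped consensus tree, with fixed output schemas and
# a checksummed manifest.

#' Subset an alignment to a set of sequences
#'
#' @param aln a [labeled_alignment()].
#' @param ids sequence ids to keep (order preserved as given).
#' @return a [labeled_alignment()] over the selected sequences.
#' @export
subset_alignment <- function(aln, ids) {
  stopifnot(inherits(aln, "labeled_alignment"))
  missing <- setdiff(ids, aln$ids)
  if (length(missing)) stop("unknown id(s): ", paste(missing, collapse = ", "))
  labeled_alignment(aln$seqs[ids], ids = ids, groups = aln$groups[ids])
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline in one serializable object; the
#' effective configuration is echoed verbatim into the output directory.
#'
#' @param alignment_path path to the input alignment (MSF or FASTA).
#' @param labels_path optional path to the group-label TSV.
#' @param out_dir output directory (created if needed).
#' @param format alignment format, as in [read_alignment()].
#' @param reference_ids sequence ids used to annotate columns with
#'   reference residue numbers.
#' @param gent_method,pseudocount,common_threshold see [gent_scan()].
#' @param fe_cutoff,ge_cutoff quadrant cutoffs; `NULL` = percentile
#'   defaults.
#' @param top_n rows per ranked group-specific table.
#' @param motif_widths,n_motifs,min_separation,include_threshold,
#'   x_max_residues see [find_motifs()].
#' @param max_gap_fraction trimming cutoff, see [trim_columns()].
#' @param distance_model `"kimura"` (default) or `"p"`.
#' @param bootstrap_R bootstrap replicates (default 100).
#' @param seed seed for the bootstrap resampling.
#' @param plots also write GE-vs-FE SVG plots (default `FALSE`; plot
#'   files are excluded from determinism guarantees).
#' @return object of class `run_config`.
#' @export
run_config <- function(alignment_path, labels_path = NULL, out_dir,
                       format = "auto", reference_ids = character(0),
                       gent_method = "kl", pseudocount = 0.05,
                       common_threshold = 0.25,
                       fe_cutoff = NULL, ge_cutoff = NULL, top_n = 10L,
                       motif_widths = c(15L, 21L, 29L, 41L, 50L),
                       n_motifs = 10L, min_separation = 1L,
                       include_threshold = 0.10, x_max_residues = 4L,
                       max_gap_fraction = 0.5,
                       distance_model = "kimura", bootstrap_R = 100L,
                       seed = 1L, plots = FALSE) {
  cfg <- mget(names(formals(run_config)), environment())
  if (!file.exists(alignment_path)) {
    stop("alignment file not found: ", alignment_path)
  }
  if (!is.null(labels_path) && !file.exists(labels_path)) {
    stop("label file not found: ", labels_path)
  }
  stopifnot(bootstrap_R >= 1L, top_n >= 1L, n_motifs >= 1L)
  structure(cfg, class = "run_config")
}

aa3name <- function(letters1) {
  vapply(strsplit(letters1, ",", fixed = TRUE), function(ls) {
    if (!length(ls) || is.na(ls[1L]) || !nzchar(ls[1L])) return("")
    paste(seqinr::aaa(ls), collapse = ", ")
  }, character(1L))
}

num3 <- function(x) sprintf("%.3f", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# annotate columns with reference residue numbers ("<res>" or "-")
ref_annotation <- function(refmaps, cols) {
  out <- list()
  for (rid in names(refmaps)) {
    res <- map_index_to_ref(refmaps[[rid]], cols)
    out[[paste0("res_", rid)]] <- ifelse(is.na(res), "-", res)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Reads the alignment and labels, then writes: the per-column
#' conservation table and band summary; per-group ranked group-specific
#' tables and full GEnt dumps; the motif table; the bipartition tally,
#' majority-rule consensus newick and per-group clade-support report; the
#' echoed configuration; and a checksummed MANIFEST. Deterministic for a
#' fixed configuration and seed (plot files excepted). A stage failure
#' aborts with a stage-named error after writing a MANIFEST that marks
#' the run incomplete.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of class `gentscan_run` with the computed
#'   objects (`alignment`, `conservation`, `band_summary`, `gent`,
#'   `ranked`, `motifs`, `tallies`, `consensus`, `clade_support`,
#'   `manifest`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(out_dir = config$out_dir, config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      mark_incomplete(config$out_dir, name, conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  results$alignment <- stage("input", {
    aln <- read_alignment(config$alignment_path, config$format)
    if (!is.null(config$labels_path)) {
      aln <- set_groups(aln, read_group_labels(config$labels_path,
                                               valid_groups = NULL))
    }
    aln
  })
  aln <- results$alignment

  results$refmaps <- stage("reference_maps", {
    refs <- intersect(config$reference_ids, aln$ids)
    stats::setNames(lapply(refs, build_reference_map, aln = aln), refs)
  })

  results$conservation <- stage("conservation", classify_columns(aln))
  results$band_summary <- band_summary(results$conservation)

  bg <- background_frequencies("uniform", pseudocount = config$pseudocount)
  results$gent <- stage("gent", {
    groups <- declared_groups(aln)
    stats::setNames(lapply(groups, function(g) {
      gent_scan(aln, g, bg, config$gent_method, config$common_threshold)
    }), groups)
  })
  results$ranked <- lapply(results$gent, rank_group_specific,
                           fe_cutoff = config$fe_cutoff,
                           top_n = config$top_n)

  results$motifs <- stage("motifs", {
    find_motifs(aln, config$motif_widths, config$n_motifs,
                config$min_separation, bg, config$gent_method,
                config$include_threshold, config$x_max_residues)
  })

  results <- c(results, stage("phylogeny", {
    trimmed <- trim_columns(aln, config$max_gap_fraction)
    tl <- bootstrap_support(trimmed, config$bootstrap_R, config$seed,
                            config$distance_model)
    cons <- consensus_tree(tl)
    cs <- lapply(declared_groups(aln), group_clade_support,
                 tallies = tl, aln = aln)
    names(cs) <- declared_groups(aln)
    list(trimmed = trimmed, tallies = tl, consensus = cons,
         clade_support = cs)
  }))

  results$manifest <- stage("report", write_report(results))
  class(results) <- "gentscan_run"
  invisible(results)
}

mark_incomplete <- function(out_dir, stage, msg) {
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("MANIFEST", files)]
  df <- data.frame(file = basename(files),
                   md5 = unname(tools::md5sum(files)))
  df <- rbind(df, data.frame(file = "STATUS",
                             md5 = paste0("INCOMPLETE:", stage, ":", msg)))
  write_tsv(df, file.path(out_dir, "MANIFEST.tsv"))
}

#' Write the pipeline report files
#'
#' Serializes computed pipeline results with stable column orders and
#' headers: scores with 3 decimal places, counts as integers. Normally
#' called by [run_pipeline()].
#'
#' @param results the (partial) results list assembled by
#'   [run_pipeline()]; must contain `out_dir`, `config` and `alignment`.
#' @return data.frame manifest (`file`, `md5`) of every written artifact.
#' @export
write_report <- function(results) {
  out <- results$out_dir
  config <- results$config
  aln <- results$alignment
  written <- character(0)

  cons <- results$conservation
  df <- data.frame(col = cons$col)
  ann <- ref_annotation(results$refmaps, cons$col)
  for (nm in names(ann)) df[[nm]] <- ann[[nm]]
  df$modal_residue <- cons$modal_residue
  df$percent <- as.integer(cons$percent)
  df$band <- as.character(cons$band)
  written <- c(written, write_tsv(df, file.path(out, "conservation.tsv")))

  bs <- results$band_summary
  written <- c(written, write_tsv(
    data.frame(band = names(bs), count = as.integer(bs)),
    file.path(out, "band_summary.tsv")))

  for (g in names(results$gent)) {
    scan <- results$gent[[g]]
    full <- data.frame(Index = scan$col)
    ann <- ref_annotation(results$refmaps, scan$col)
    for (nm in names(ann)) full[[nm]] <- ann[[nm]]
    full$GroupEntropy <- num3(scan$GE)
    full$FamilyEntropy <- num3(scan$FE)
    full$HighestGroupResidue <- aa3name(scan$highest_group_residue)
    for (cc in grep("^common_", names(scan), value = TRUE)) {
      full[[paste0("Common", sub("^common_", "", cc), "Residue")]] <-
        aa3name(scan[[cc]])
    }
    written <- c(written, write_tsv(
      full, file.path(out, paste0("gent_full_", g, ".tsv"))))
    ranked <- results$ranked[[g]]
    written <- c(written, write_tsv(
      full[match(ranked$col, scan$col), , drop = FALSE],
      file.path(out, paste0("gent_", g, ".tsv"))))
  }

  mot <- results$motifs
  idx <- if (nrow(mot)) paste0(mot$start_col, "-", mot$end_col)
         else character(0)
  written <- c(written, write_tsv(
    data.frame(motif = mot$motif, length = mot$length,
               pattern = mot$pattern, indices = idx,
               score = num3(mot$score)),
    file.path(out, "motifs.tsv")))

  if (!is.null(results$tallies)) {
    tl <- results$tallies
    ord <- order(-tl$counts, names(tl$counts))
    written <- c(written, write_tsv(
      data.frame(split = names(tl$counts)[ord],
                 count = as.integer(tl$counts[ord]),
                 frequency = num3(tl$counts[ord] / tl$R_used)),
      file.path(out, "bipartitions.tsv")))
    ape::write.tree(results$consensus, file.path(out, "consensus.nwk"))
    written <- c(written, file.path(out, "consensus.nwk"))
    cs <- results$clade_support
    written <- c(written, write_tsv(
      data.frame(group = vapply(cs, `[[`, character(1L), "group"),
                 n = vapply(cs, `[[`, numeric(1L), "n"),
                 support = vapply(cs, `[[`, numeric(1L), "support"),
                 R_used = vapply(cs, `[[`, numeric(1L), "R_used"),
                 monophyletic = vapply(cs, `[[`, logical(1L),
                                       "monophyletic"),
                 largest_pure_fraction = num3(
                   vapply(cs, `[[`, numeric(1L), "largest_pure_fraction"))),
      file.path(out, "clade_support.tsv")))
  }

  if (isTRUE(config$plots)) {
    for (g in names(results$gent)) {
      f <- file.path(out, paste0("gent_", g, ".svg"))
      grDevices::svg(f, width = 7, height = 5)
      plot(results$gent[[g]], fe_cutoff = config$fe_cutoff,
           ge_cutoff = config$ge_cutoff)
      grDevices::dev.off()
      written <- c(written, f)
    }
  }

  cfg <- config
  class(cfg) <- NULL
  cfg <- lapply(cfg, function(v) if (is.null(v)) "default" else v)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  written <- c(written, file.path(out, "config.yaml"))

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  write_tsv(manifest, file.path(out, "MANIFEST.tsv"))
  manifest
}

#' @export
print.gentscan_run <- function(x, ...) {
  cat("gentscan pipeline run -> ", x$out_dir, "\n", sep = "")
  cat("Sequences: ", length(x$alignment$ids), "; columns: ",
      x$alignment$n_columns, "\n", sep = "")
  bs <- x$band_summary
  cat("Bands: ", paste(names(bs), bs, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("Artifacts: ", nrow(x$manifest), " files (see MANIFEST.tsv)\n",
      sep = "")
  invisible(x)
}
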