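# End-to-end driver: a YAML-serializable run configuration and run_all(),
# which executes simulate (optional) -> align -> conserve (frames 0/1/2) ->
# model -> positions -> properties, writing every table as TSV with a
# provenance comment block (package version, configuration checksum, seed).
# Outputs carry no timestamps, so a rerun with the same configuration and
# inputs is byte-identical.

#' Read and validate a run configuration
#'
#' @param path YAML file. Recognized fields: `species` (vector), `reference`,
#'   `code_table` (1/12), `pseudocount` (`"auto"` or number), `outlier_k`,
#'   `min_species`, `seed`, `focal_pairs`, `control_pairs`, `n_sets`,
#'   `set_size`, and either `simulate:` (fields of [synthetic_spec()]) or
#'   `inputs:` with `orf_fasta` (named per-species paths), `ortholog_table`
#'   and optional `exclude_file` / `property_table`.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(code_table = 1L, pseudocount = "auto", outlier_k = 3,
                   min_species = NULL, seed = 1L,
                   focal_pairs = default_planted_pairs(),
                   control_pairs = NULL, n_sets = 100L, set_size = 9L)
  for (f in names(defaults)) {
    if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config must provide either 'simulate' or 'inputs'")
  }
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$code_table <- cfg$code_table
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cfg$sim_spec <- do.call(synthetic_spec, sim_args)
    cfg$species <- paste0("sp", seq_len(cfg$sim_spec$n_species))
    cfg$reference <- "sp1"
  }
  if (is.null(cfg$species) || is.null(cfg$reference)) {
    stop("config must name 'species' and 'reference'")
  }
  if (!cfg$reference %in% cfg$species) {
    stop("reference species '", cfg$reference, "' is not in species list")
  }
  if (is.null(cfg$min_species)) {
    cfg$min_species <- max(2L, length(cfg$species) - 1L)
  }
  structure(cfg, class = "run_config")
}

# order-insensitive checksum of the configuration for provenance stamping
config_checksum <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", prov), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_seed <- function(root_seed, stage) {
  (as.integer(root_seed) +
     sum(utf8ToInt(stage) * seq_len(nchar(stage)))) %% 2147483647L
}

#' Run the whole conservation pipeline
#'
#' Executes the configured stages and writes all result tables into
#' `out_dir`. Each TSV starts with `#` provenance comments (package version,
#' configuration checksum, stage seed); a rerun with identical configuration
#' and inputs reproduces the files byte for byte.
#'
#' @param config A `run_config` (from [read_run_config()] or
#'   [validate_run_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_all <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- paste0("paircons ",
                 as.character(utils::packageVersion("paircons")),
                 "; config=", config_checksum(cfg), "; seed=", cfg$seed)
  code <- load_genetic_code(cfg$code_table)

  # ---- inputs: simulate or read ----
  sim <- NULL
  if (!is.null(cfg$sim_spec)) {
    sim <- generate_orthologs(cfg$sim_spec)
    write_synthetic(sim, file.path(out_dir, "synthetic"))
    alignments <- as_codon_alignments(
      sim, method = if (cfg$sim_spec$indel_prob > 0) "align" else "truth")
  } else {
    seqs <- lapply(cfg$inputs$orf_fasta, read_fasta)
    skel <- read_ortholog_table(cfg$inputs$ortholog_table, cfg$species,
                                reference = cfg$reference)
    if (!is.null(cfg$inputs$exclude_file)) {
      skel <- apply_orf_filter(skel, read_orf_filter(cfg$inputs$exclude_file),
                               cfg$reference)
    }
    groups <- build_ortholog_groups(skel, seqs, code)
    alignments <- lapply(groups, align_group, code = code,
                         reference = cfg$reference)
  }

  # ---- conservation, frames 0/1/2 ----
  tab0 <- accumulate_conservation(alignments, code)
  tab1 <- shifted_frame_conservation(alignments, 1L)
  tab2 <- shifted_frame_conservation(alignments, 2L)
  orf_rates <- orf_conservation_rates(alignments)
  write_tsv_prov(tab0$codons, file.path(out_dir, "conservation_codons.tsv"), prov)
  write_tsv_prov(tab0$pairs[, c("codon1", "codon2", "total", "conserved", "rate")],
                 file.path(out_dir, "conservation_pairs.tsv"), prov)
  write_tsv_prov(orf_rates, file.path(out_dir, "orf_rates.tsv"), prov)

  # ---- pair model ----
  fit <- fit_origin_line(tab0)
  outl <- call_outliers(fit, cfg$outlier_k)
  scores <- normalized_scores(tab0, cfg$pseudocount)
  zt <- dipeptide_zscores(scores, code)
  ranks <- rank_within_dipeptide(tab0, code, by = "raw_rate")
  fitdf <- fit$pairs
  fitdf$outlier <- ifelse(fitdf$pair %in% outl$above, "above",
                          ifelse(fitdf$pair %in% outl$below, "below", "no"))
  write_tsv_prov(fitdf, file.path(out_dir, "pair_fit.tsv"),
                 c(prov, paste0("slope=", format(fit$slope, digits = 12),
                                "; residual_sigma=",
                                format(fit$residual_sigma, digits = 12))))
  write_tsv_prov(scores$scores, file.path(out_dir, "normalized_scores.tsv"),
                 c(prov, paste0("pseudocount=",
                                format(scores$pseudocount, digits = 12))))
  write_tsv_prov(zt$z_table, file.path(out_dir, "dipeptide_z.tsv"), prov)
  write_tsv_prov(ranks, file.path(out_dir, "dipeptide_ranks.tsv"), prov)

  # ---- frame-shift control ----
  fsc <- frame_shift_control(list(tab0, tab1, tab2), cfg$focal_pairs, code,
                             cfg$pseudocount)
  write_tsv_prov(fsc, file.path(out_dir, "frameshift_z.tsv"), prov)

  # ---- positions ----
  occ <- collect_occurrences(alignments, cfg$focal_pairs)
  write_tsv_prov(occ, file.path(out_dir, "occurrences.tsv"), prov)
  all_occ <- collect_occurrences(alignments, sense_pairs(code))
  sim_sum <- simulate_random_sets(all_occ, cfg$n_sets, cfg$set_size,
                                  seed = stage_seed(cfg$seed, "positions"),
                                  universe = sense_pairs(code),
                                  exclude = normalize_pair(cfg$focal_pairs))
  write_tsv_prov(data.frame(set = seq_along(sim_sum$medians),
                            median_position = sim_sum$medians),
                 file.path(out_dir, "simulation_summary.tsv"),
                 c(prov,
                   paste0("n_sets=", sim_sum$n_sets,
                          "; set_size=", sim_sum$set_size,
                          "; mean_of_medians=",
                          format(sim_sum$mean_of_medians, digits = 12),
                          "; sd_of_medians=",
                          format(sim_sum$sd_of_medians, digits = 12))))

  # ---- gene properties (optional) ----
  props <- NULL
  sets <- NULL
  if (!is.null(cfg$control_pairs)) {
    sets <- define_orf_sets(alignments, cfg$focal_pairs, cfg$control_pairs,
                            cfg$min_species)
    props <- if (!is.null(sim)) {
      emit_property_table(sim, seed = stage_seed(cfg$seed, "properties"))
    } else if (!is.null(cfg$inputs$property_table)) {
      utils::read.delim(cfg$inputs$property_table, comment.char = "#",
                        stringsAsFactors = FALSE)
    }
    if (!is.null(props)) {
      res <- summarize_sets(props, sets[c("focal", "control", "other")])
      write_tsv_prov(res$summary, file.path(out_dir, "table1_like.tsv"), prov)
      write_tsv_prov(res$ks, file.path(out_dir, "property_ks.tsv"), prov)
      if ("polysome" %in% names(props)) {
        cnt <- t(vapply(sets[c("focal", "control", "other")], function(ids) {
          table(factor(props$polysome[match(ids, props$orf_id)],
                       levels = sort(unique(props$polysome))))
        }, numeric(length(unique(props$polysome)))))
        chi <- tryCatch(chisq_categories(cnt), error = function(e) NULL)
        if (!is.null(chi)) {
          write_tsv_prov(data.frame(statistic = chi$statistic, df = chi$df,
                                    p.value = chi$p.value),
                         file.path(out_dir, "polysome_chisq.tsv"), prov)
        }
      }
    }
  }

  invisible(list(alignments = alignments, conservation = tab0,
                 frame1 = tab1, frame2 = tab2, orf_rates = orf_rates,
                 fit = fit, outliers = outl, scores = scores, z = zt,
                 ranks = ranks, frameshift = fsc, occurrences = occ,
                 simulation = sim_sum, sim = sim, sets = sets,
                 properties = props))
}
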