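# End-to-end synthetic study: generate N truly-null gap-avoiding track
# pairs, test each pair under the gap-ignorant and/or gap-aware null
# model, BH-correct each mode separately across the study's pairs, count
# false rejections, and summarize p-value uniformity.

#' Configure a synthetic gap-bias study
#'
#' The genome can be given either as a [genome_sim_spec()] (simulated as
#' part of the run, seeded from the study seed) or as an explicit
#' `genome` + `gaps` pair (e.g. read from chrom.sizes and a gap BED).
#'
#' @param genome_spec a [genome_sim_spec()], or `NULL` when `genome` and
#'   `gaps` are supplied.
#' @param genome,gaps explicit [genome()] and gap `interval_set`.
#' @param n_pairs number of truly-null track pairs to generate and test.
#' @param track_spec_a,track_spec_b [track_sim_spec()]s for the two tracks
#'   of every pair (`track_spec_b` defaults to `track_spec_a`).
#' @param modes subset of `c("whole_genome", "exclude_gaps")` to run.
#' @param mc_samples Monte Carlo shuffles per test.
#' @param fdr_alpha BH false discovery rate threshold (default 0.05).
#' @param seed master seed; all pair and test seeds derive from it via
#'   [derive_seed()], so the two modes are compared on identical pairs.
#' @return an object of class `study_config`.
#' @export
study_config <- function(genome_spec = NULL, genome = NULL, gaps = NULL,
                         n_pairs = 100,
                         track_spec_a, track_spec_b = track_spec_a,
                         modes = c("whole_genome", "exclude_gaps"),
                         mc_samples = 99, fdr_alpha = 0.05, seed = 1) {
  modes <- match.arg(modes, c("whole_genome", "exclude_gaps"),
                     several.ok = TRUE)
  stopifnot(n_pairs >= 1, fdr_alpha > 0, fdr_alpha < 1,
            inherits(track_spec_a, "track_sim_spec"),
            inherits(track_spec_b, "track_sim_spec"))
  if (is.null(genome_spec)) {
    stopifnot(inherits(genome, "genome"))
    if (is.null(gaps)) gaps <- empty_interval_set("gaps")
  } else {
    stopifnot(inherits(genome_spec, "genome_sim_spec"))
  }
  structure(
    list(genome_spec = genome_spec, genome = genome, gaps = gaps,
         n_pairs = as.integer(n_pairs),
         track_spec_a = track_spec_a, track_spec_b = track_spec_b,
         modes = modes, mc_samples = as.integer(mc_samples),
         fdr_alpha = fdr_alpha, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Named study presets
#'
#' High-power presets for the two study conditions:
#' \describe{
#'   \item{`"hg19-histone-like"`}{22 chromosomes totalling 3.0 Gbp, 7.6%
#'     of bases in gaps, 100 pairs of 50,000 elements x 2,114 bp.}
#'   \item{`"hg38-dnase-like"`}{22 chromosomes totalling 3.1 Gbp, 5% of
#'     bases in gaps, 95 pairs of 50,000 elements x 4,000 bp.}
#' }
#' `scale` shrinks the genome and the per-track element count together
#' (gap fraction and segment length unchanged), giving desk-scale runs
#' with the same placement geometry.
#'
#' @param name preset name.
#' @param scale scaling factor in `(0, 1]` for chromosome length and
#'   element count.
#' @param modes,mc_samples,seed see [study_config()].
#' @return a [study_config()].
#' @export
study_preset <- function(name = c("hg19-histone-like", "hg38-dnase-like"),
                         scale = 1,
                         modes = c("whole_genome", "exclude_gaps"),
                         mc_samples = 99, seed = 1) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  par <- switch(name,
    "hg19-histone-like" = list(total = 3.0e9, gap_fraction = 0.076,
                               n_pairs = 100L, n_elements = 50000,
                               segment_length = 2114),
    "hg38-dnase-like" = list(total = 3.1e9, gap_fraction = 0.05,
                             n_pairs = 95L, n_elements = 50000,
                             segment_length = 4000)
  )
  gs <- genome_sim_spec(
    n_chromosomes = 22,
    chromosome_length = round(par$total / 22 * scale),
    gap_fraction = par$gap_fraction
  )
  ts <- track_sim_spec(
    n_elements = round(par$n_elements * scale),
    segment_length_law = list(law = "fixed", length = par$segment_length),
    avoid_gaps = TRUE
  )
  cfg <- study_config(genome_spec = gs, n_pairs = par$n_pairs,
                      track_spec_a = ts, modes = modes,
                      mc_samples = mc_samples, seed = seed)
  cfg$preset <- name
  cfg$scale <- scale
  cfg
}

#' Run a gap-bias study end to end
#'
#' For each pair `i`, draws a truly-null pair via [simulate_null_pair()]
#' (seeded from the master seed and `i`), runs [mc_coloc_test()] on the
#' same pair under every requested null mode (each mode with its own
#' derived seed), applies [bh_fdr()] separately per mode, and computes
#' rejection counts and the Kolmogorov-Smirnov uniformity diagnostic of
#' the p-values. Fully reproducible given the config.
#'
#' @param config a [study_config()].
#' @param checkpoint_dir optional directory: per-pair rows are appended to
#'   `partial_results.tsv` as they complete, and on error a
#'   `failure_manifest.json` records how far the run got before the error
#'   is rethrown.
#' @return an object of class `study_result` with `per_pair` (one row per
#'   pair x mode: observed/null mean/ratio/p/q/rejected), `summary` (one
#'   row per mode: `n_rejected`, KS statistic and p, statistic means),
#'   `genome`, `gaps` and a config echo.
#' @export
run_study <- function(config, checkpoint_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  if (!is.null(config$genome_spec)) {
    sim <- simulate_genome(config$genome_spec, seed = derive_seed(seed, 0))
    genome <- sim$genome
    gaps <- sim$gaps
  } else {
    genome <- config$genome
    gaps <- config$gaps
  }
  modes <- config$modes
  specs <- lapply(modes, function(md) {
    null_model_spec(md,
                    gaps = if (md == "exclude_gaps") gaps else NULL,
                    mc_samples = config$mc_samples)
  })
  names(specs) <- modes
  ckpt_file <- NULL
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt_file <- file.path(checkpoint_dir, "partial_results.tsv")
    if (file.exists(ckpt_file)) unlink(ckpt_file)
  }
  rows <- vector("list", config$n_pairs * length(modes))
  ri <- 0L
  run_core <- function() {
    for (i in seq_len(config$n_pairs)) {
      pair <- simulate_null_pair(config$track_spec_a, config$track_spec_b,
                                 genome, gaps, seed = derive_seed(seed, i))
      for (mi in seq_along(modes)) {
        res <- mc_coloc_test(pair$a, pair$b, genome, specs[[mi]],
                             seed = derive_seed(seed, i, mi))
        ri <<- ri + 1L
        rows[[ri]] <<- data.frame(
          pair = i, mode = modes[mi],
          observed_bp = res$observed_bp,
          null_mean_bp = res$null_mean_bp,
          enrichment_ratio = res$enrichment_ratio,
          p_value = res$p_value,
          stringsAsFactors = FALSE
        )
        if (!is.null(ckpt_file)) {
          write.table(rows[[ri]], ckpt_file, sep = "\t", quote = FALSE,
                      row.names = FALSE, col.names = !file.exists(ckpt_file),
                      append = file.exists(ckpt_file))
        }
      }
    }
  }
  if (is.null(checkpoint_dir)) {
    run_core()
  } else {
    tryCatch(run_core(), error = function(e) {
      jsonlite::write_json(
        list(error = conditionMessage(e), completed_rows = ri,
             n_pairs = config$n_pairs, modes = modes, seed = seed),
        file.path(checkpoint_dir, "failure_manifest.json"),
        auto_unbox = TRUE)
      stop(e)
    })
  }
  per_pair <- do.call(rbind, rows)
  per_pair$q_value <- NA_real_
  per_pair$rejected <- NA
  summ <- vector("list", length(modes))
  for (mi in seq_along(modes)) {
    idx <- per_pair$mode == modes[mi]
    q <- bh_fdr(per_pair$p_value[idx])
    per_pair$q_value[idx] <- q
    per_pair$rejected[idx] <- q < config$fdr_alpha
    ks <- suppressWarnings(ks.test(per_pair$p_value[idx], "punif"))
    summ[[mi]] <- data.frame(
      mode = modes[mi],
      n_pairs = sum(idx),
      n_rejected = sum(q < config$fdr_alpha),
      ks_stat = unname(ks$statistic),
      ks_p = ks$p.value,
      mean_observed_bp = mean(per_pair$observed_bp[idx]),
      mean_null_mean_bp = mean(per_pair$null_mean_bp[idx]),
      mean_enrichment_ratio = mean(per_pair$enrichment_ratio[idx]),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(per_pair = per_pair, summary = do.call(rbind, summ),
         genome = genome, gaps = gaps,
         config = list(
           preset = config$preset %||% NA,
           scale = config$scale %||% NA,
           n_pairs = config$n_pairs, modes = modes,
           mc_samples = config$mc_samples, fdr_alpha = config$fdr_alpha,
           seed = seed,
           n_elements_a = config$track_spec_a$n_elements,
           n_elements_b = config$track_spec_b$n_elements,
           segment_length_law_a = config$track_spec_a$segment_length_law,
           segment_length_law_b = config$track_spec_b$segment_length_law,
           genome_total_bp = genome$total,
           gap_total_bp = total_bp(gaps),
           gap_fraction = total_bp(gaps) / genome$total
         )),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d truly-null pair(s), m = %d, FDR alpha = %g\n",
              x$config$n_pairs, x$config$mc_samples, x$config$fdr_alpha))
  cat(sprintf("  genome %.3g bp, gaps %.3g bp (%.2f%%)\n",
              x$config$genome_total_bp, x$config$gap_total_bp,
              100 * x$config$gap_fraction))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-13s: %d/%d rejected; KS %.3f (p = %.3g); mean ratio %.3f\n",
                s$mode, s$n_rejected, s$n_pairs, s$ks_stat, s$ks_p,
                s$mean_enrichment_ratio))
  }
  invisible(x)
}

#' Write study reports
#'
#' Emits, under `outdir`: `per_pair.tsv` (one row per pair x mode),
#' `summary.json` (rejection counts, KS diagnostics, config echo, seed;
#' re-parses to the in-memory values), a p-value histogram per null mode,
#' and a paired observed-vs-null-mean plot. TSV/JSON output is
#' deterministic: re-running on the same result is byte-identical.
#'
#' @param result a [run_study()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
report_study <- function(result, outdir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- character(0)
  tsv <- file.path(outdir, "per_pair.tsv")
  write.table(result$per_pair, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, tsv)
  js <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(summary = result$summary, config = result$config),
    js, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, js)
  for (md in unique(result$per_pair$mode)) {
    f <- file.path(outdir, paste0("pvalues_", md, ".pdf"))
    df <- result$per_pair[result$per_pair$mode == md, ]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = p_value)) +
      ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                              fill = "grey35", colour = "white") +
      ggplot2::labs(title = paste0("MC p-values under the ", md, " null"),
                    x = "p-value", y = "pairs") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(f, p, width = 5, height = 3.5)
    paths <- c(paths, f)
  }
  f <- file.path(outdir, "observed_vs_null.pdf")
  p <- ggplot2::ggplot(result$per_pair,
                       ggplot2::aes(x = null_mean_bp,
                                    y = observed_bp)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::facet_wrap(~mode, scales = "free") +
    ggplot2::labs(x = "null mean overlap (bp)", y = "observed overlap (bp)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(f, p, width = 7, height = 3.5)
  paths <- c(paths, f)
  invisible(paths)
}

#' Read a study configuration from a YAML file
#'
#' Flat key-value mirror of [study_config()]: keys `n_pairs`, `modes`,
#' `mc_samples`, `fdr_alpha`, `seed`, a `genome` block (either
#' `chrom_sizes` + `gaps_bed` paths, or `n_chromosomes`,
#' `chromosome_length`, `gap_fraction`) and a `track` block
#' (`n_elements`, `segment_length`, optional `avoid_gaps`).
#'
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$track), !is.null(y$genome))
  ts <- track_sim_spec(
    n_elements = y$track$n_elements,
    segment_length_law = list(law = "fixed",
                              length = y$track$segment_length),
    avoid_gaps = y$track$avoid_gaps %||% TRUE
  )
  args <- list(
    n_pairs = y$n_pairs %||% 100,
    track_spec_a = ts,
    modes = y$modes %||% c("whole_genome", "exclude_gaps"),
    mc_samples = y$mc_samples %||% 99,
    fdr_alpha = y$fdr_alpha %||% 0.05,
    seed = y$seed %||% 1
  )
  if (!is.null(y$genome$chrom_sizes)) {
    args$genome <- read_chrom_sizes(y$genome$chrom_sizes)
    args$gaps <- if (!is.null(y$genome$gaps_bed)) {
      read_bed(y$genome$gaps_bed, genome = args$genome, label = "gaps")
    } else NULL
  } else {
    args$genome_spec <- genome_sim_spec(
      n_chromosomes = y$genome$n_chromosomes,
      chromosome_length = y$genome$chromosome_length,
      gap_fraction = y$genome$gap_fraction
    )
  }
  do.call(study_config, args)
}
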