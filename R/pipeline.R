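#' Pipeline configuration
#'
#' Builds (or loads from YAML) the single flat configuration driving
#' [run_pipeline()]. Explicit arguments override file values, which
#' override package defaults.
#'
#' @param path Optional YAML file with configuration keys.
#' @param ... Named overrides of any configuration field: `window_size`
#'   (5000), `step` (`window_size`), `quantile` (0.95), `min_sites` (3),
#'   `max_missing` (0.10), `min_maf` (0.10), `flank` (5000), `max_gap`
#'   (0), `alpha_assoc` (0.01), `alpha_enrich` (0.05), `alpha_deg`
#'   (0.05), `fold_thr` (2), `seed` (1), plus the [sim_config()] fields
#'   under `sim`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    window_size = 5000, step = NULL, quantile = 0.95, min_sites = 3,
    max_missing = 0.10, min_maf = 0.10, flank = 5000, max_gap = 0,
    alpha_assoc = 0.01, alpha_enrich = 0.05, alpha_deg = 0.05,
    fold_thr = 2, seed = 1L, sim = list()
  )
  from_file <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), overrides)
  if (is.null(cfg$step)) cfg$step <- cfg$window_size
  with(cfg, {
    if (quantile <= 0 || quantile >= 1) {
      abort("quantile must lie in (0, 1)", class = "sweepscan_validation_error")
    }
    if (window_size <= 0 || step <= 0) {
      abort("window_size and step must be positive",
        class = "sweepscan_validation_error")
    }
    if (any(c(max_missing, min_maf) < 0 | c(max_missing, min_maf) > 1)) {
      abort("filters must lie in [0, 1]", class = "sweepscan_validation_error")
    }
  })
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' The file round-trips losslessly through [pipeline_config()].
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Deterministic per-stage seed: master seed offset by a stable integer
# hash of the stage name, kept inside the 32-bit range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * (seq_len(nchar(stage)) * 131L)) %% 1000003L
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}

#' Run the full synthetic study end to end
#'
#' Executes simulate -> filter -> scan -> sweep thresholding/regions/genes
#' -> tree and grouping -> allele association -> effect classification ->
#' enrichment -> otolith calls -> qPCR -> DEG on synthetic data, writing
#' every stage's outputs under `out_dir` along with a `MANIFEST.tsv`
#' carrying the configuration hash, the master seed and an MD5 checksum
#' per file. Reruns with identical configuration produce identical
#' checksums. On stage failure the partial outputs are retained and the
#' MANIFEST names the failed stage.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param dry_run When `TRUE`, print and return the resolved stage plan
#'   without writing anything.
#' @return Invisibly, a list with the in-memory stage results plus
#'   `manifest` (tibble). For `dry_run`, the character vector of stages.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = "sweepscan_run",
                         dry_run = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- c("simulate", "filter", "scan", "sweep", "tree", "assoc",
              "effects", "enrich", "otolith", "qpcr", "deg")
  if (dry_run) {
    cat("sweepscan pipeline plan:\n",
        paste0("  ", seq_along(stages), ". ", stages, collapse = "\n"),
        "\n", sep = "")
    return(invisible(stages))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(cfg))
  manifest <- tibble(stage = character(), file = character(),
                     md5 = character())
  note <- function(stage, path) {
    manifest <<- bind_rows(manifest, tibble(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path))))
  }
  state <- list(config = cfg)
  current <- NA_character_
  t0 <- Sys.time()

  run_stage <- function(stage, fn) {
    current <<- stage
    t_start <- Sys.time()
    fn()
    inform(sprintf("[%s] done in %.1fs", stage,
                   as.numeric(Sys.time() - t_start, units = "secs")))
  }

  result <- tryCatch({
    run_stage("simulate", function() {
      sim_cfg <- do.call(sim_config, utils::modifyList(
        list(seed = stage_seed(cfg$seed, "simulate")), cfg$sim))
      sim <- simulate_dataset(sim_cfg)
      state$sim_cfg <<- sim_cfg
      state$sim <<- sim
      state$ref <<- simulate_reference(sim_cfg, sim$dataset)
      state$ann <<- simulate_annotation(sim_cfg)
      state$term_map <<- simulate_term_map(
        state$ann, seed = stage_seed(cfg$seed, "terms"))
      note("simulate", write_vcf(sim$dataset,
                                 file.path(out_dir, "genotypes.vcf")))
      note("simulate", write_fasta(state$ref,
                                   file.path(out_dir, "reference.fa")))
      note("simulate", write_gff3(state$ann,
                                  file.path(out_dir, "annotation.gff3")))
      p <- file.path(out_dir, "truth_sweeps.bed")
      note("simulate", write_bed(sim$truth$sweeps, p))
      p <- file.path(out_dir, "grouping_truth.tsv")
      readr::write_tsv(sim$grouping, p); note("simulate", p)
    })
    run_stage("filter", function() {
      state$filtered <<- filter_variants(
        state$sim$dataset, cfg$max_missing, cfg$min_maf)
      cts <- attr(state$filtered, "counts")
      inform(sprintf("[filter] %d -> %d sites (%d missing, %d maf)",
                     cts$n_input, cts$n_kept, cts$n_removed_missing,
                     cts$n_removed_maf))
      p <- file.path(out_dir, "genotypes_filtered.vcf")
      note("filter", write_vcf(state$filtered, p))
    })
    run_stage("scan", function() {
      state$windows <<- scan_windows(
        state$filtered, state$sim$grouping,
        window_size = cfg$window_size, step = cfg$step,
        min_sites = cfg$min_sites,
        chrom_lengths = state$sim_cfg$chrom_lengths)
      p <- file.path(out_dir, "windows.tsv")
      note("scan", write_window_table(state$windows, p))
    })
    run_stage("sweep", function() {
      state$sweeps <<- call_sweeps(
        state$windows, q = cfg$quantile, max_gap = cfg$max_gap,
        ann = state$ann)
      p <- file.path(out_dir, "selected_windows.tsv")
      readr::write_tsv(state$sweeps$selected, p, na = "NA"); note("sweep", p)
      p <- file.path(out_dir, "sweep_regions.bed")
      note("sweep", write_bed(state$sweeps$regions, p))
      p <- file.path(out_dir, "candidate_genes.tsv")
      readr::write_tsv(state$sweeps$genes, p); note("sweep", p)
    })
    run_stage("tree", function() {
      D <- ibs_distance(state$filtered)
      state$tree <<- neighbor_joining(D)
      state$grouping_called <<- tree_grouping(state$tree)
      p <- file.path(out_dir, "distances.tsv")
      note("tree", write_distance_matrix(D, p))
      p <- file.path(out_dir, "nj_tree.nwk")
      writeLines(write_newick(state$tree), p); note("tree", p)
      p <- file.path(out_dir, "grouping_called.tsv")
      readr::write_tsv(state$grouping_called, p); note("tree", p)
    })
    run_stage("assoc", function() {
      state$assoc <<- allele_assoc_scan(
        state$filtered, state$sim$grouping, alpha = cfg$alpha_assoc)
      p <- file.path(out_dir, "allele_assoc.tsv")
      readr::write_tsv(state$assoc, p); note("assoc", p)
    })
    run_stage("effects", function() {
      state$effects <<- classify_effects(
        state$filtered, state$ann, state$ref, flank = cfg$flank)
      p <- file.path(out_dir, "effects.tsv")
      readr::write_tsv(state$effects, p, na = "NA"); note("effects", p)
    })
    run_stage("enrich", function() {
      state$enrich <<- enrich_terms(
        state$sweeps$genes$gene_id, state$ann$gene_id, state$term_map,
        alpha = cfg$alpha_enrich)
      p <- file.path(out_dir, "enrichment.tsv")
      readr::write_tsv(state$enrich, p); note("enrich", p)
    })
    run_stage("otolith", function() {
      seeds <- stage_seed(cfg$seed, "otolith") + 0:9
      calls <- bind_rows(lapply(seq_along(seeds), function(i) {
        pattern <- if (i %% 2 == 0) "resident" else "migratory"
        tr <- simulate_otolith(pattern, seed = seeds[i])
        tibble(fish = sprintf("fish_%02d", i), truth = pattern,
               called = classify_life_history(tr))
      }))
      state$otolith <<- calls
      p <- file.path(out_dir, "otolith_calls.tsv")
      readr::write_tsv(calls, p); note("otolith", p)
    })
    run_stage("qpcr", function() {
      q <- simulate_qpcr(seed = stage_seed(cfg$seed, "qpcr"))
      dd <- ddct_relative_expression(q)
      state$qpcr <<- dd
      p <- file.path(out_dir, "qpcr_rq.tsv")
      readr::write_tsv(dd$samples, p); note("qpcr", p)
    })
    run_stage("deg", function() {
      # small synthetic expression table: 50 genes, 5 with a planted
      # four-fold increase in the migratory group
      set.seed(stage_seed(cfg$seed, "deg"))
      n_genes <- 50; n_per <- 5
      base <- matrix(2^rnorm(n_genes * 2 * n_per, 6, 0.3), nrow = n_genes)
      base[1:5, 1:n_per] <- base[1:5, 1:n_per] * 4
      expr <- as_tibble(as.data.frame(base))
      names(expr) <- c(sprintf("mig_%d", 1:n_per), sprintf("fw_%d", 1:n_per))
      expr <- dplyr::bind_cols(
        tibble(gene_id = sprintf("g%03d", 1:n_genes)), expr)
      grp <- tibble(sample_id = names(expr)[-1],
                    group = rep(c("migratory", "freshwater"), each = n_per))
      state$deg <<- call_deg(expr, grp, fold_thr = cfg$fold_thr,
                             alpha = cfg$alpha_deg)
      p <- file.path(out_dir, "deg_flags.tsv")
      readr::write_tsv(state$deg, p); note("deg", p)
    })
    list(ok = TRUE)
  }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))

  manifest_path <- file.path(out_dir, "MANIFEST.tsv")
  header <- c(
    sprintf("# sweepscan pipeline; config_hash=%s; seed=%d", cfg_hash,
            as.integer(cfg$seed)),
    sprintf("# status=%s%s",
            if (result$ok) "ok" else "failed",
            if (result$ok) "" else paste0("; failed_stage=", current))
  )
  writeLines(c(header, paste(c("stage", "file", "md5"), collapse = "\t"),
               paste(manifest$stage, manifest$file, manifest$md5,
                     sep = "\t")),
             manifest_path)
  if (!result$ok) {
    abort(sprintf("pipeline failed at stage '%s': %s", current,
                  result$error),
      class = "sweepscan_pipeline_error")
  }
  inform(sprintf("pipeline complete in %.1fs; outputs in %s",
                 as.numeric(Sys.time() - t0, units = "secs"), out_dir))
  state$manifest <- manifest
  invisible(state)
}
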