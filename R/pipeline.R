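#' Pipeline configuration
#'
#' Assembles the full analysis configuration with every stage parameter
#' defaulted and recorded; all values, including untouched defaults, are
#' echoed into the run manifest so a run is reconstructible from manifest +
#' inputs.
#'
#' @param input_prefix PLINK path stem
#' @param format `"ped"` or `"bed"`
#' @param output_dir directory for reports (created if absent)
#' @param seed global seed (drives the CSS reference draw)
#' @param breed_labels optional sidecar data.frame (sample_id, breed)
#'   overriding the family-ID column
#' @param stages character vector of stages to run, from
#'   `c("filter", "pca", "fst", "inbreeding", "roh", "ne", "css")`
#' @param autosome_max,pca_k,roh,roh_bins_mb,ne_breed,ne_args,css_target,
#'   css_args stage parameter blocks (see the stage functions)
#' @param haps optional `haplotype_set` for the XP-EHH component of the CSS
#'   stage (without it the degraded two-statistic combination is used)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input_prefix, format = c("ped", "bed"),
                            output_dir, seed = 1L,
                            breed_labels = NULL,
                            stages = c("filter", "pca", "fst", "inbreeding",
                                       "roh", "ne", "css"),
                            autosome_max = 26L,
                            pca_k = 10L,
                            roh = roh_params(),
                            roh_bins_mb = c(1, 5, 10, 20, 40),
                            ne_breed = NULL,
                            ne_args = list(min_dist_bp = 5e4, max_dist_bp = 4e6,
                                           maf_min = 0.05, bins = 30L,
                                           mapping = "linear", alpha = 2.2,
                                           beta = 1, cm_per_mb = 1,
                                           min_pairs = 50L),
                            css_target = NULL,
                            css_args = list(n_per_ref_breed = 5L,
                                            smooth_window_bp = 1e6,
                                            top_frac_a = 0.001,
                                            top_frac_b = 0.01,
                                            flank_bp = 5e5, min_support = 5L,
                                            peak_score = "smoothed"),
                            haps = NULL) {
  format <- match.arg(format)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_file <- function(dir, name) file.path(dir, paste0(name, ".tsv"))

#' Run the full breed-genomics pipeline
#'
#' Executes, in order: variant filtering, then the differentiation stage
#' (PCA and pairwise weighted F_ST), the inbreeding stage (heterozygosity F,
#' ROH, F_ROH, length-class summary, Kruskal-Wallis / pairwise Wilcoxon
#' comparisons), the LD-based N_e trajectory per breed, and — if a target
#' breed is configured — the composite selection scan with peak calling.
#' Every stage writes TSV reports into `output_dir`, and a manifest records
#' the seed, every stage parameter (defaults included) and per-stage row
#' counts. Identical config + seed gives identical outputs. A stage failure
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list of the in-memory stage results (and writes the
#'   report files)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, input_prefix = config$input_prefix,
                   format = config$format, stages = config$stages)
  results <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dataset <- run_stage("read", function() read_plink(config$input_prefix, config$format))
  if (!is.null(config$breed_labels)) {
    i <- match(dataset$samples$sample_id, config$breed_labels$sample_id)
    dataset$samples$breed <- config$breed_labels$breed[i]
  }

  if ("filter" %in% config$stages) {
    fl <- run_stage("filter", function() filter_variants(dataset, config$autosome_max))
    dataset <- fl$dataset
    write_filter_report(fl$report, stage_file(config$output_dir, "filter_report"))
    manifest$filter <- c(autosome_max = config$autosome_max,
                         unclass(fl$report))
    results$filter <- fl$report
  }

  if ("pca" %in% config$stages) {
    pc <- run_stage("pca", function() pca_genotypes(dataset, config$pca_k))
    data.table::fwrite(
      data.frame(sample_id = rownames(pc$scores),
                 breed = dataset$samples$breed, pc$scores),
      stage_file(config$output_dir, "pca_scores"), sep = "\t")
    data.table::fwrite(
      data.frame(component = seq_along(pc$variance_explained),
                 variance_explained = pc$variance_explained),
      stage_file(config$output_dir, "pca_variance"), sep = "\t")
    manifest$pca <- list(k = config$pca_k, n_snps_used = pc$n_snps_used)
    results$pca <- pc
  }

  if ("fst" %in% config$stages) {
    fst <- run_stage("fst", function() pairwise_fst(dataset))
    write_fst_matrix(fst, stage_file(config$output_dir, "fst_matrix"))
    manifest$fst <- list(n_breeds = length(fst$breeds))
    results$fst <- fst
  }

  if ("inbreeding" %in% config$stages) {
    hf <- run_stage("inbreeding", function() het_inbreeding(dataset))
    data.table::fwrite(hf, stage_file(config$output_dir, "het_f"), sep = "\t")
    results$het_f <- hf
    if (length(unique(dataset$samples$breed)) >= 2L &&
        all(table(dataset$samples$breed) >= 3L)) {
      cmp <- run_stage("inbreeding", function() {
        compare_groups(hf$f_hat, dataset$samples$breed)
      })
      data.table::fwrite(cmp$pairwise,
                         stage_file(config$output_dir, "het_f_pairwise"), sep = "\t")
      manifest$het_f_kruskal <- cmp$kruskal
      results$het_f_comparison <- cmp
    }
    manifest$inbreeding <- list(n_samples = nrow(hf))
  }

  if ("roh" %in% config$stages) {
    seg <- run_stage("roh", function() detect_roh(dataset, config$roh))
    data.table::fwrite(seg, stage_file(config$output_dir, "roh_segments"), sep = "\t")
    fr <- froh(seg, dataset)
    data.table::fwrite(fr, stage_file(config$output_dir, "froh"), sep = "\t")
    ls <- roh_length_summary(seg, dataset, config$roh_bins_mb)
    data.table::fwrite(ls, stage_file(config$output_dir, "roh_length_summary"),
                       sep = "\t")
    manifest$roh <- c(unclass(config$roh),
                      list(bins_mb = config$roh_bins_mb, n_segments = nrow(seg)))
    results$roh <- seg; results$froh <- fr; results$roh_summary <- ls
  }

  if ("ne" %in% config$stages) {
    breeds <- if (is.null(config$ne_breed)) unique(dataset$samples$breed)
              else config$ne_breed
    results$ne <- list()
    for (b in breeds) {
      nb <- sum(dataset$samples$breed == b)
      if (nb < 10L) next
      tr <- run_stage("ne", function() {
        a <- config$ne_args
        ld <- pairwise_r2(dataset, b, a$min_dist_bp, a$max_dist_bp, a$maf_min)
        ne_trajectory(ld, bins = a$bins, mapping = a$mapping, alpha = a$alpha,
                      beta = a$beta, cm_per_mb = a$cm_per_mb,
                      min_pairs = a$min_pairs)
      })
      data.table::fwrite(tr, stage_file(config$output_dir,
                                        paste0("ne_trajectory_", b)), sep = "\t")
      results$ne[[b]] <- tr
    }
    manifest$ne <- config$ne_args
  }

  if ("css" %in% config$stages && !is.null(config$css_target)) {
    css <- run_stage("css", function() {
      a <- config$css_args
      design <- make_contrast(dataset, config$css_target,
                              a$n_per_ref_breed, seed = config$seed)
      fst_c <- snp_fst_contrast(dataset, design)
      dsaf <- delta_saf(dataset, design)
      xp <- if (!is.null(config$haps)) {
        xpehh(config$haps, design)$xpehh_norm
      } else NULL
      tab <- css_combine(dataset, fst_c, dsaf, xp)
      tab <- smooth_css(tab, a$smooth_window_bp)
      regions <- call_peaks(tab, a$top_frac_a, a$top_frac_b, a$flank_bp,
                            a$min_support, score = a$peak_score)
      list(table = tab, regions = regions, design = design)
    })
    data.table::fwrite(css$table, stage_file(config$output_dir, "css_table"),
                       sep = "\t")
    data.table::fwrite(css$regions, stage_file(config$output_dir, "css_regions"),
                       sep = "\t")
    manifest$css <- c(config$css_args,
                      list(target = config$css_target,
                           statistics = paste(attr(css$table, "statistics"),
                                              collapse = "+"),
                           n_regions = nrow(css$regions)))
    results$css <- css
  }

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null", force = TRUE),
             file.path(config$output_dir, "manifest.json"))
  invisible(results)
}
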