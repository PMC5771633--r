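#' Pipeline configuration
#'
#' Validates and assembles a configuration for [run_pipeline()]. Exactly
#' one of `profile` (synthetic run) or `alignment`/`groups` paths (real
#' input) must be supplied. All randomness (bootstrap resampling,
#' synthetic generation) flows from `seed`.
#'
#' @param profile A [plant_profile()] for a synthetic run, or the string
#'   `"festuca"` for the packaged preset.
#' @param alignment,groups Paths to an aligned FASTA and a taxon/group TSV
#'   (real-input run).
#' @param ssr An SSR table (tibble or TSV path); for the `"festuca"`
#'   preset it defaults to [festuca_ssr_table()].
#' @param stages Stages to run, a subset of `"variants"`, `"compare"`,
#'   `"diagnose"`, `"ssr"`, `"trees"`, `"network"`, `"date"`.
#' @param diagnostic_groups Length-2 group pair for diagnostic marker
#'   discovery.
#' @param reference_taxon Reference for binary encoding (defaults to the
#'   first taxon).
#' @param ancestral,descendants Ancestor node id and descendant taxa for
#'   the `date` stage (`NULL` skips dating even when the stage is listed).
#' @param bootstrap_replicates,epsilon,weight,mutation_rate,min_indel_length,ssr_min_fragments,tolerance
#'   Stage parameters; the defaults mirror the study's settings (1000
#'   replicates, epsilon 0, character weight 10, 20,180 yr/mutation).
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory for the report bundle.
#' @returns A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = NULL, alignment = NULL, groups = NULL,
                            ssr = NULL,
                            stages = c("variants", "compare", "diagnose",
                                       "ssr", "trees", "network", "date"),
                            diagnostic_groups = c("Continental",
                                                  "Mediterranean"),
                            reference_taxon = NULL,
                            ancestral = NULL, descendants = NULL,
                            bootstrap_replicates = 1000L, epsilon = 0,
                            weight = 10, mutation_rate = 20180,
                            min_indel_length = 3L, ssr_min_fragments = 2L,
                            tolerance = 0L, seed, out_dir = tempfile("bundle")) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (identical(profile, "festuca")) profile <- festuca_profile(seed = seed)
  synthetic <- !is.null(profile)
  real <- !is.null(alignment) || !is.null(groups)
  if (synthetic == real) {
    abort("supply exactly one of `profile` or `alignment`+`groups`")
  }
  known <- c("variants", "compare", "diagnose", "ssr", "trees", "network",
             "date")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(sprintf("unknown stage(s): %s",
                                     paste(bad, collapse = ", ")))
  structure(
    list(profile = profile, alignment = alignment, groups = groups,
         ssr = ssr, stages = stages,
         diagnostic_groups = diagnostic_groups,
         reference_taxon = reference_taxon,
         ancestral = ancestral, descendants = descendants,
         parameters = list(bootstrap_replicates = bootstrap_replicates,
                           epsilon = epsilon, weight = weight,
                           mutation_rate = mutation_rate,
                           min_indel_length = min_indel_length,
                           ssr_min_fragments = ssr_min_fragments,
                           tolerance = tolerance, seed = as.integer(seed)),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML fields mirror the arguments of [pipeline_config()]; a
#' synthetic run uses `profile: festuca`.
#'
#' @param path YAML file.
#' @returns A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order - variant calling, the
#' group-comparison table, diagnostic indel discovery, SSR discrimination
#' scoring, Dice/UPGMA and TN93/UPGMA bootstrap trees, the median-joining
#' network and rho clade ages - and writes one artifact per stage into the
#' bundle directory, plus a run log recording every parameter. Identical
#' config and seed reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @returns A `report_bundle`: list with `tables` (tibbles/objects per
#'   stage), `artifacts` (file paths) and `log` (the log file path).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$parameters
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(
    sprintf("fescuephylo %s | R %s",
            as.character(utils::packageVersion("fescuephylo")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("stages: %s", paste(config$stages, collapse = ", ")),
    paste(sprintf("%s = %s", names(p), unlist(p)), collapse = "; ")
  )
  tables <- list()
  artifacts <- character()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s",
                                      stage, conditionMessage(e))), log_path)
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  # inputs
  truth <- NULL
  if (!is.null(config$profile)) {
    sim <- run_stage("simulate", generate_alignment(config$profile))
    aln <- sim$alignment
    truth <- sim$truth
    ssr_tab <- config$ssr
    if (is.null(ssr_tab) && "ssr" %in% config$stages) {
      ssr_tab <- festuca_ssr_table(seed = p$seed)$table
    }
  } else {
    aln <- run_stage("load",
                     read_alignment_fasta(config$alignment, config$groups))
    ssr_tab <- config$ssr
    if (is.character(ssr_tab)) {
      ssr_tab <- readr::read_tsv(ssr_tab, show_col_types = FALSE)
    }
  }
  groups <- aln$groups
  ref <- config$reference_taxon %||% aln$taxa[1L]
  save_tbl <- function(x, name, writer = readr::write_tsv) {
    path <- file.path(config$out_dir, name)
    writer(x, path)
    artifacts[[name]] <<- path
  }

  loci <- NULL
  if (any(c("variants", "compare", "diagnose", "trees", "network", "date")
          %in% config$stages)) {
    loci <- run_stage("variants", call_variants(aln))
  }
  if ("variants" %in% config$stages) {
    tables$variants <- loci
    run_stage("variants", save_tbl(loci, "variants.tsv", write_variant_tsv))
    log_lines <- c(log_lines, sprintf("variants: %d loci (%s)", nrow(loci),
                                      paste(names(table(loci$class)),
                                            table(loci$class),
                                            sep = ":", collapse = ", ")))
  }
  if ("compare" %in% config$stages) {
    cmp <- run_stage("compare", comparison_table(loci, groups))
    tables$comparison <- cmp
    run_stage("compare", save_tbl(cmp, "comparison.csv", readr::write_csv))
  }
  if ("diagnose" %in% config$stages) {
    dg <- config$diagnostic_groups
    diag_tbl <- run_stage("diagnose",
      find_diagnostic_indels(loci, groups, dg[1L], dg[2L],
                             min_length = p$min_indel_length,
                             tolerance = p$tolerance))
    tables$diagnostic_indels <- diag_tbl
    run_stage("diagnose", save_tbl(diag_tbl, "diagnostic_indels.tsv"))
  }
  if ("ssr" %in% config$stages && !is.null(ssr_tab)) {
    dg <- config$diagnostic_groups
    ssr_rep <- run_stage("ssr",
      score_ssr_discrimination(ssr_tab, groups, dg[1L], dg[2L],
                               min_fragments = p$ssr_min_fragments,
                               tolerance = p$tolerance))
    tables$ssr <- ssr_rep
    run_stage("ssr", save_tbl(ssr_rep, "ssr_discrimination.tsv"))
  }
  if ("trees" %in% config$stages) {
    band <- run_stage("trees", encode_binary(loci, encoding = "band"))
    dice_tree <- run_stage("trees",
      bootstrap_support(band, "dice", n_replicates = p$bootstrap_replicates,
                        seed = p$seed))
    tn_tree <- run_stage("trees",
      bootstrap_support(aln, "tn93", n_replicates = p$bootstrap_replicates,
                        seed = p$seed + 1L))
    tables$dice_tree <- dice_tree
    tables$tn93_tree <- tn_tree
    run_stage("trees", save_tbl(dice_tree, "dice_upgma.nwk", write_newick))
    run_stage("trees", save_tbl(tn_tree, "tn93_upgma.nwk", write_newick))
  }
  net <- NULL
  if (any(c("network", "date") %in% config$stages)) {
    refmat <- run_stage("network",
                        encode_binary(loci, reference_taxon = ref))
    net <- run_stage("network",
                     median_joining(refmat, epsilon = p$epsilon,
                                    weight = p$weight))
    tables$network <- net
    if ("network" %in% config$stages) {
      run_stage("network", save_tbl(net, "network.gml", write_network_gml))
      run_stage("network",
                save_tbl(net, "network_edges.tsv", write_network_edges))
    }
  }
  if ("date" %in% config$stages && !is.null(config$ancestral)) {
    age <- run_stage("date",
      rho_age(net, config$ancestral, config$descendants,
              mutation_rate = p$mutation_rate))
    tables$age <- age
    run_stage("date", save_tbl(tidy.age_estimate(age), "clade_age.tsv"))
  }
  writeLines(log_lines, log_path)
  structure(list(tables = tables, artifacts = artifacts, log = log_path,
                 truth = truth, config = config),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d artifact(s) in %s\n",
              length(x$artifacts), x$config$out_dir))
  for (nm in names(x$artifacts)) cat("  -", nm, "\n")
  invisible(x)
}
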