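# End-to-end orchestration: simulate -> classify -> model -> features ->
# enrich, with a JSON run manifest. Plain files plus a manifest (no
# workflow engine): the pipeline is linear and desk-scale. Output bytes
# are a deterministic function of the config.

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest and used for the
#'   simulation stage.
#' @param sim_params a [simulation_params()] (its seed is overridden by
#'   `seed`); `NULL` disables the simulate stage, in which case `paths`
#'   must point at existing inputs.
#' @param paths named list of input paths when not simulating:
#'   `gff3` (character vector), `orthogroups`, `unassigned`, `anchors`,
#'   `expression`, `terms`.
#' @param W proximity window (bp) for the classify stage.
#' @param mode `"dual"` or `"orthogroup"` classification.
#' @param digits percentage decimals in summaries.
#' @param min_count enrichment term floor.
#' @param stages stages to run, in order.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, sim_params = simulation_params(
                         n_accessions = 6, n_orthogroups = 500, seed = seed),
                       paths = list(), W = 5000, mode = c("dual", "orthogroup"),
                       digits = 2, min_count = 3,
                       stages = c("simulate", "classify", "model", "features",
                                  "enrich", "report")) {
  mode <- match.arg(mode)
  if (!is.null(sim_params)) sim_params$seed <- as.integer(seed)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim_params = sim_params,
              paths = paths, W = W, mode = mode, digits = digits,
              min_count = min_count, stages = stages)
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(stage, t0) {
  message(sprintf("[vpav] stage %-9s %6.2fs", stage, as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline
#'
#' Executes the configured stages, writing all tables under
#' `config$out_dir` and a `manifest.json` recording the package version,
#' seed, parameters, input checksums and (for simulated runs) the gene-label
#' accuracy against the generator truth. A stage failure aborts with the
#' failing stage named. Reruns with identical config produce byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed_comment <- sprintf("seed=%d", config$seed)
  truth <- NULL
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    t0 <- as.numeric(Sys.time())
    tryCatch(fun(), error = function(e) {
      stopf("stage %s failed: %s", stage, conditionMessage(e))
    })
    stage_log(stage, t0)
  }

  inputs <- config$paths
  run_stage("simulate", function() {
    sim_dir <- file.path(out, "sim")
    truth <<- simulate_pangenome(config$sim_params, sim_dir)
    inputs <<- list(
      gff3 = file.path(sim_dir, paste0(truth$accessions, ".gff3")),
      orthogroups = file.path(sim_dir, "Orthogroups.tsv"),
      unassigned = file.path(sim_dir, "Orthogroups_UnassignedGenes.tsv"),
      anchors = file.path(sim_dir, "anchors.tsv"),
      expression = file.path(sim_dir, "expression.tsv"),
      terms = file.path(sim_dir, "terms.tsv")
    )
  })

  run_stage("classify", function() {
    for (req in c("gff3", "orthogroups")) {
      if (is.null(inputs[[req]]) || !all(file.exists(inputs[[req]]))) {
        stopf("input '%s' not found", req)
      }
    }
    if (config$mode == "dual" &&
        (is.null(inputs$anchors) || !file.exists(inputs$anchors))) {
      stopf("anchors file not found (required for mode 'dual')")
    }
    anns <- lapply(inputs$gff3, read_gff3)
    accs <- vapply(anns, `[[`, "", "accession_id")
    tbl <- read_orthogroups(inputs$orthogroups, inputs$unassigned, accessions = accs)
    anch <- if (config$mode == "dual") read_anchors(inputs$anchors, accessions = accs)
    labels <- classify_pav(tbl, anns, anch, W = config$W, mode = config$mode)
    state$annotations <- anns
    state$table <- tbl
    state$labels <- labels
    write_table(labels$units[order(unit_id)], file.path(out, "unit_labels.tsv"),
                comments = seed_comment)
    write_table(labels$gene_labels[order(global), .(accession, gene_id, label)],
                file.path(out, "gene_labels.tsv"), comments = seed_comment)
    s <- summarize_pav(labels, digits = config$digits)
    write_table(s$per_accession, file.path(out, "summary_per_accession.tsv"),
                comments = seed_comment)
    write_table(data.table(mean_core = s$overall$mean_core,
                           mean_total = s$overall$mean_total,
                           pct_core = s$overall$pct_core,
                           pct_aux = s$overall$pct_aux,
                           units_core = s$units$n_core,
                           units_total = s$units$n_total,
                           units_pct_core = s$units$pct_core),
                file.path(out, "summary_overall.tsv"), comments = seed_comment)
  })

  run_stage("model", function() {
    if (is.null(state$labels)) stopf("classification results unavailable")
    for (u in c("orthogroup", "gene")) {
      cv <- model_curve(state$labels, unit = u)
      write_table(cv, file.path(out, sprintf("curve_%s.tsv", u)),
                  comments = c(seed_comment, sprintf("open=%s", attr(cv, "open"))))
    }
  })

  run_stage("features", function() {
    if (is.null(state$labels)) stopf("classification results unavailable")
    expr <- if (!is.null(inputs$expression) && file.exists(inputs$expression)) {
      read_expression(inputs$expression)
    }
    ft <- compute_features(state$annotations, state$labels, expr)
    state$features <- ft
    write_table(ft[order(global)], file.path(out, "features.tsv"),
                comments = seed_comment)
    write_table(compare_all_features(ft), file.path(out, "feature_comparison.tsv"),
                comments = seed_comment)
  })

  run_stage("enrich", function() {
    if (is.null(state$labels)) stopf("classification results unavailable")
    if (is.null(inputs$terms) || !file.exists(inputs$terms)) {
      stopf("term map not found")
    }
    tm <- read_term_map(inputs$terms)
    og_terms <- terms_by_orthogroup(tm, state$table)
    un <- state$labels$units
    enr <- term_enrichment(og_terms,
                           foreground = un[label == "auxiliary", unit_id],
                           universe = un$unit_id,
                           min_count = config$min_count)
    write_table(enr, file.path(out, "enrichment_auxiliary.tsv"),
                comments = seed_comment)
  })

  # manifest: everything needed to reproduce the run
  manifest <- list(
    package = "vpav",
    version = as.character(packageVersion("vpav")),
    seed = config$seed,
    W = config$W,
    mode = config$mode,
    stages = config$stages,
    sim_params = if (!is.null(config$sim_params)) {
      p <- unclass(config$sim_params)
      p$enrich_params <- as.data.frame(p$enrich_params)
      p
    },
    input_md5 = {
      files <- unlist(inputs)
      md5 <- tools::md5sum(files)
      # key by path relative to out_dir so reruns in different locations match
      root <- paste0(normalizePath(out, winslash = "/", mustWork = FALSE), "/")
      nm <- normalizePath(files, winslash = "/", mustWork = FALSE)
      names(md5) <- ifelse(startsWith(nm, root), substring(nm, nchar(root) + 1), files)
      as.list(md5)
    }
  )
  if (!is.null(truth) && !is.null(state$labels)) {
    tl <- merge(state$labels$gene_labels[, .(global, label)],
                truth$genes[, .(global, class)], by = "global")
    manifest$label_accuracy <- mean(tl$label == tl$class)
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  run_stage("report", function() {
    writeLines(pav_report(out), file.path(out, "report.md"))
  })
  invisible(out)
}

#' Markdown digest of a pipeline run
#'
#' Reads the tables a [run_pipeline()] call wrote and renders a short
#' digest: core/auxiliary percentages, the accumulation curve, feature
#' medians and the top enrichment hits.
#'
#' @param out_dir a pipeline output directory.
#' @param top number of enrichment rows shown.
#' @return character vector of markdown lines.
#' @export
pav_report <- function(out_dir, top = 5) {
  lines <- c("# Pangenome run digest", "")
  f <- function(...) file.path(out_dir, ...)
  md_table <- function(dt) {
    dt <- as.data.table(dt)
    txt <- vapply(dt, function(col) {
      if (is.double(col)) formatC(col, digits = 6, format = "g") else as.character(col)
    }, FUN.VALUE = character(nrow(dt)))
    if (nrow(dt) == 1) txt <- matrix(txt, nrow = 1)
    c(paste0("| ", paste(names(dt), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(dt)), collapse = "|"), "|"),
      apply(txt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }
  if (file.exists(f("summary_overall.tsv"))) {
    s <- read_table(f("summary_overall.tsv"))
    lines <- c(lines, "## Classification", "",
               sprintf("Mean per-accession: %.1f core of %.1f genes (%s%% core, %s%% auxiliary).",
                       s$mean_core, s$mean_total, format(s$pct_core), format(s$pct_aux)),
               sprintf("Units: %d core of %d (%s%%).",
                       s$units_core, s$units_total, format(s$units_pct_core)), "")
  }
  if (file.exists(f("curve_orthogroup.tsv"))) {
    cv <- read_table(f("curve_orthogroup.tsv"))
    lines <- c(lines, "## Accumulation curve (orthogroup units)", "", md_table(cv), "")
  }
  if (file.exists(f("feature_comparison.tsv"))) {
    fc <- read_table(f("feature_comparison.tsv"))
    lines <- c(lines, "## Core vs auxiliary features", "",
               md_table(fc[, c("feature", "n_core", "n_aux", "median_core",
                               "median_aux", "U", "p", "direction")]), "")
  }
  if (file.exists(f("enrichment_auxiliary.tsv"))) {
    en <- read_table(f("enrichment_auxiliary.tsv"))
    lines <- c(lines, "## Auxiliary-set term enrichment", "")
    if (nrow(en) == 0) {
      lines <- c(lines, "no terms pass min_count", "")
    } else {
      lines <- c(lines, md_table(utils::head(en, top)), "")
    }
  }
  lines
}
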