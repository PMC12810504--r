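# End-to-end orchestration: a config (YAML file or list) names the inputs
# and thresholds per stage; run_pipeline() executes whichever stages the
# config covers, writes TSV/JSON outputs and a manifest, and make_report()
# condenses a run directory into one JSON + text summary.

default_config <- function() {
  list(min_sources = 2L, min_agreement = 2L, overlap_policy = "all_drugs",
       kappa_threshold = 0.3, min_hits = 2L,
       mcode = list(node_score_cutoff = 0.2, k_core = 2L, haircut = TRUE,
                    fluff = FALSE, max_depth = 100L),
       seed = 1L)
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  for (f in c("source_lists", "drug_targets", "edge_table", "annotation",
              "hits", "universe", "trrust")) {
    if (!is.null(cfg[[f]])) {
      missing <- cfg[[f]][!file.exists(unlist(cfg[[f]]))]
      if (length(missing) > 0L) {
        np_stop("config input for '%s' does not exist: %s", f,
                paste(missing, collapse = ", "))
      }
    }
  }
  if (is.null(cfg$out_dir)) np_stop("config must name an out_dir")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline from a config
#'
#' Executes, in order and as far as the config's inputs allow: evidence
#' fusion, drug-target consensus, disease overlap, network construction,
#' topology panel, MCODE, fragility, enrichment with term clustering, and
#' TF overlay. Every stage writes its TSV/JSON outputs under
#' `config$out_dir`; a `manifest.json` records the completed stages, config
#' hash and seed. A stage failure stops the run with prior outputs retained
#' and the manifest marking the failed stage.
#'
#' Config fields (all paths are input files; any subset of stages may be
#' configured): `source_lists` (named list source -> gene-list file),
#' `min_sources`; `drug_targets` (TSV drug/predictor/gene), `min_agreement`,
#' `overlap_policy`; `edge_table` (+ optional `edge_dialect`); `hubs`
#' (vector, for fragility); `annotation` (GMT), `hits` (gene-list file),
#' `universe` (gene-list file), `min_hits`, `kappa_threshold`; `trrust`
#' (TF table) and `key_genes`; `mcode` (parameter list); `seed`; `out_dir`.
#'
#' @param config path to a YAML file, or an equivalent named list
#' @return the run directory path, invisibly; `manifest.json` inside it
#'   lists completed stages
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  stages <- character(0)
  manifest <- list(package_version = as.character(utils::packageVersion("netpharm")),
                   config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list(), failed_stage = NULL)
  finish <- function() {
    manifest$stages <- as.list(stages)
    write_json(manifest, file.path(cfg$out_dir, "manifest.json"))
  }
  run_stage <- function(name, expr) {
    ok <- tryCatch({ expr; TRUE }, error = function(e) {
      manifest$failed_stage <<- list(stage = name, error = conditionMessage(e))
      finish()
      np_stop("stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages <<- c(stages, name)
    invisible(ok)
  }

  if (!is.null(cfg$hubs) && is.null(cfg$edge_table)) {
    np_stop("fragility requested (hubs given) but no edge_table configured")
  }

  disease <- NULL
  if (!is.null(cfg$source_lists)) run_stage("evidence", {
    sets <- mapply(load_gene_list, unlist(cfg$source_lists),
                   names(cfg$source_lists), SIMPLIFY = FALSE)
    mat <- multi_evidence_intersect(sets, cfg$min_sources)
    disease <- mat$gene
    write_evidence(mat, file.path(cfg$out_dir, "evidence_retained.tsv"),
                   file.path(cfg$out_dir, "evidence_venn.json"))
  })

  if (!is.null(cfg$drug_targets)) run_stage("consensus", {
    preds <- load_drug_targets(cfg$drug_targets)
    cons <- consensus_by_drug(preds, cfg$min_agreement)
    df <- do.call(rbind, lapply(names(cons), function(d)
      if (length(cons[[d]])) data.frame(drug = d, gene = cons[[d]])))
    write_tsv(df, file.path(cfg$out_dir, "consensus_targets.tsv"))
    if (!is.null(disease)) {
      ov <- disease_overlap(cons, disease, cfg$overlap_policy)
      writeLines(ov$shared, file.path(cfg$out_dir, "shared_genes.txt"))
      write_json(list(policy = ov$policy, shared = ov$shared,
                      per_drug = ov$per_drug),
                 file.path(cfg$out_dir, "overlap.json"))
    }
  })

  net <- NULL
  if (!is.null(cfg$edge_table)) {
    run_stage("network", {
      net <- build_network(cfg$edge_table, cfg$edge_dialect %||% "tsv")
    })
    run_stage("topology", {
      write_topology(net, file.path(cfg$out_dir, "node_metrics.tsv"),
                     file.path(cfg$out_dir, "metric_panel.json"))
    })
    run_stage("mcode", {
      cx <- do.call(find_complexes, c(list(net), cfg$mcode))
      write_complexes(cx, file.path(cfg$out_dir, "complexes.tsv"),
                      file.path(cfg$out_dir, "complexes.json"))
    })
    if (!is.null(cfg$hubs)) run_stage("fragility", {
      rep <- fragility_analysis(net, unlist(cfg$hubs))
      write_fragility(rep, file.path(cfg$out_dir, "fragility.tsv"),
                      file.path(cfg$out_dir, "fragility.json"))
    })
  }

  if (!is.null(cfg$annotation) && !is.null(cfg$universe)) run_stage("enrichment", {
    ann <- read_gmt(cfg$annotation)
    universe <- normalize_symbols(readLines(cfg$universe, warn = FALSE))
    hits <- if (!is.null(cfg$hits)) {
      normalize_symbols(readLines(cfg$hits, warn = FALSE))
    } else disease
    if (is.null(hits)) np_stop("enrichment needs 'hits' or an evidence stage")
    rows <- enrich(hits, ann, universe, cfg$min_hits)
    cl <- if (nrow(rows) > 0L) {
      cluster_terms(rows, ann, cfg$kappa_threshold, domain = hits)
    }
    write_enrichment(rows, cl, file.path(cfg$out_dir, "enrichment.tsv"))
  })

  if (!is.null(cfg$trrust) && !is.null(cfg$key_genes)) run_stage("tf_overlay", {
    regs <- load_trrust(cfg$trrust)
    net_genes <- if (!is.null(net)) igraph::V(net)$name else
      unique(unlist(lapply(regs, `[[`, "targets")))
    extra <- if (!is.null(cfg$universe)) {
      normalize_symbols(readLines(cfg$universe, warn = FALSE))
    } else character(0)
    universe <- unique(c(net_genes, unlist(lapply(regs, `[[`, "targets")), extra))
    cov <- tf_coverage(regs, unlist(cfg$key_genes), net_genes, universe)
    write_tsv(cov, file.path(cfg$out_dir, "tf_coverage.tsv"))
  })

  finish()
  invisible(cfg$out_dir)
}

#' Summarize a completed run directory
#'
#' Collects every stage output present in `run_dir` into one JSON report
#' plus a plain-text summary reproducing the hub ranking and the
#' metrics-by-removal fragility matrix. Missing stages are listed as
#' absent, not errors.
#'
#' @param run_dir directory produced by [run_pipeline()]
#' @return path of the JSON report, invisibly
#' @export
make_report <- function(run_dir) {
  grab_tsv <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) read.delim(p, check.names = FALSE) else NULL
  }
  grab_json <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) jsonlite::read_json(p) else NULL
  }
  report <- list(
    manifest = grab_json("manifest.json"),
    evidence_venn = grab_json("evidence_venn.json"),
    hub_ranking = grab_tsv("node_metrics.tsv"),
    metric_panel = grab_json("metric_panel.json"),
    complexes = grab_tsv("complexes.tsv"),
    fragility_matrix = grab_tsv("fragility.tsv"),
    enrichment = grab_tsv("enrichment.tsv"),
    tf_coverage = grab_tsv("tf_coverage.tsv"))
  absent <- names(report)[vapply(report, is.null, logical(1))]
  report$absent_sections <- absent
  json_path <- file.path(run_dir, "report.json")
  write_json(report, json_path)
  txt <- c("netpharm run report", sprintf("run directory: %s", run_dir), "")
  if (!is.null(report$hub_ranking)) {
    txt <- c(txt, "Hub ranking (degree / betweenness / closeness):",
             utils::capture.output(print(report$hub_ranking)), "")
  }
  if (!is.null(report$fragility_matrix)) {
    txt <- c(txt, "Fragility matrix (metric x removal):",
             utils::capture.output(print(report$fragility_matrix)), "")
  }
  if (length(absent)) txt <- c(txt, paste("absent sections:", paste(absent, collapse = ", ")))
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(json_path)
}
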