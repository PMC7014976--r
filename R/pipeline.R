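#' Default run configuration
#'
#' Returns the full nested list of per-stage parameters used by
#' [run_pipeline()]. Any subset can be overridden through a YAML file or a
#' list; unknown entries are rejected.
#'
#' @param seed Integer seed for the whole run.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulation = list(),                       # overrides for simulation_config()
    balance = list(max_iter = 200, tol = 1e-6, min_nnz = 1, mask_quantile = 0.02),
    compartments = list(min_bins = 10),
    domains = list(method = "insulation", window = 5e4, oe_floor = 1.2),
    loops = list(peak_width = 1, donut_width = 5, fdr = 0.05, min_sep = 2,
                 min_fold = 2),
    diffhic = list(pseudocount = 1, span = 0.4, fdr = 0.05),
    enrich = list(max_fdr = 0.05, min_fold = 2),
    profile = list(n_genes = 2, flank = 5e5)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file; top-level keys as in [default_run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]])) utils::modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
  }
  cfg
}

pipeline_stages <- c("simulate", "balance", "compartments", "domains",
                     "loops", "diffhic", "enrich", "profile", "report")

need_state <- function(state, what, producer) {
  if (is.null(state[[what]])) {
    stop(sprintf("missing upstream result '%s': run the '%s' stage first",
                 what, producer), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run one pipeline stage
#'
#' Stages consume the in-memory `state` produced by earlier stages and
#' write their artifacts (TSV/BED/BEDPE/bedGraph) under `out_dir`. A
#' missing upstream result raises an error naming the stage that produces
#' it.
#'
#' @param name One of `simulate`, `balance`, `compartments`, `domains`,
#'   `loops`, `diffhic`, `enrich`, `profile`, `report`.
#' @param cfg A `run_config` list (see [default_run_config()]).
#' @param out_dir Output directory.
#' @param state State list from previous stages (empty for `simulate`).
#' @return The updated state list.
#' @export
run_stage <- function(name, cfg, out_dir, state = list()) {
  name <- match.arg(name, pipeline_stages)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  if (name == "simulate") {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = cfg$seed), cfg$simulation))
    sim <- simulate_pair(sim_cfg)
    state$sim_cfg <- sim_cfg
    state$sim <- sim
    write_contacts(sim$cm1, p("contacts_cond1.tsv"))
    write_contacts(sim$cm2, p("contacts_cond2.tsv"))
    write_bed(dplyr::mutate(tibble::as_tibble(sim$genes), name = .data$gene,
                            score = 0), p("genes.bed"))
    readr::write_tsv(tibble::as_tibble(sim$degs), p("degs.tsv"), progress = FALSE)
    write_truth(sim$truth, p("truth"))
  } else if (name == "balance") {
    need_state(state, "sim", "simulate")
    a <- cfg$balance
    state$b1 <- balance(state$sim$cm1, a$max_iter, a$tol, a$min_nnz, a$mask_quantile)
    state$b2 <- balance(state$sim$cm2, a$max_iter, a$tol, a$min_nnz, a$mask_quantile)
    state$oe1 <- oe_transform(state$b1)
    state$oe2 <- oe_transform(state$b2)
    readr::write_tsv(state$b1$pixels, p("balanced_cond1.tsv"), progress = FALSE)
    readr::write_tsv(state$b2$pixels, p("balanced_cond2.tsv"), progress = FALSE)
  } else if (name == "compartments") {
    need_state(state, "oe1", "balance")
    state$track1 <- call_compartments(state$oe1, state$sim$genes,
                                      min_bins = cfg$compartments$min_bins)
    state$track2 <- call_compartments(state$oe2, state$sim$genes,
                                      min_bins = cfg$compartments$min_bins)
    state$comp_cmp <- compare_compartments(state$track1, state$track2)
    export_eigen_track(state$track1, p("eigen_cond1.bedgraph"), p("compartments_cond1.bed"))
    export_eigen_track(state$track2, p("eigen_cond2.bedgraph"), p("compartments_cond2.bed"))
    write_bed(dplyr::mutate(attr(state$comp_cmp, "changed_regions"),
                            name = "changed-compartment"),
              p("changed_compartments.bed"))
  } else if (name == "domains") {
    need_state(state, "b1", "balance")
    a <- cfg$domains
    state$dom1 <- call_domains(state$b1, method = a$method, window = a$window,
                               oe_floor = a$oe_floor)
    state$dom2 <- call_domains(state$b2, method = a$method, window = a$window,
                               oe_floor = a$oe_floor)
    state$dom_cmp <- compare_domains(state$dom1, state$dom2)
    write_bed(dplyr::mutate(tibble::as_tibble(state$dom1), name = "domain"),
              p("domains_cond1.bed"))
    write_bed(dplyr::mutate(tibble::as_tibble(state$dom2), name = "domain"),
              p("domains_cond2.bed"))
    write_bed(dplyr::mutate(state$dom_cmp$bins, name = .data$class),
              p("domain_classes.bed"))
  } else if (name == "loops") {
    need_state(state, "b1", "balance")
    a <- cfg$loops
    state$loops1 <- call_loops(state$b1, peak_width = a$peak_width,
                               donut_width = a$donut_width, fdr = a$fdr,
                               min_sep = a$min_sep, min_fold = a$min_fold)
    state$loops2 <- call_loops(state$b2, peak_width = a$peak_width,
                               donut_width = a$donut_width, fdr = a$fdr,
                               min_sep = a$min_sep, min_fold = a$min_fold)
    state$loop_cmp <- compare_loops(state$loops1, state$loops2)
    g <- state$b1$genome
    write_bedpe(dplyr::mutate(tibble::as_tibble(state$loops1), name = "loop",
                              score = .data$fold), g, p("loops_cond1.bedpe"))
    write_bedpe(dplyr::mutate(tibble::as_tibble(state$loops2), name = "loop",
                              score = .data$fold), g, p("loops_cond2.bedpe"))
  } else if (name == "diffhic") {
    need_state(state, "sim", "simulate")
    a <- cfg$diffhic
    tab <- md_table(state$sim$cm1, state$sim$cm2, pseudocount = a$pseudocount)
    tab <- loess_joint_normalize(tab, span = a$span)
    state$dc <- detect_differential(tab, fdr = a$fdr)
    g <- attr(tab, "genome")
    write_bedpe(dplyr::mutate(state$dc$hits, name = "differential",
                              score = .data$Z), g, p("differential_pixels.bedpe"))
    write_bed(dplyr::mutate(state$dc$regions, name = "differential-region"),
              p("differential_regions.bed"))
  } else if (name == "enrich") {
    need_state(state, "dc", "diffhic")
    need_state(state, "comp_cmp", "compartments")
    need_state(state, "dom_cmp", "domains")
    a <- cfg$enrich
    classes <- region_class_map(state$comp_cmp, state$dom_cmp)
    degs <- filter_degs(state$sim$degs, a$max_fdr, a$min_fold)
    res <- dplyr::bind_rows(
      dplyr::mutate(enrich_genes_in_classes(degs, state$sim$genes, classes,
                                            "comp_class"),
                    unit = "DEG", dimension = "compartment"),
      dplyr::mutate(enrich_genes_in_classes(degs, state$sim$genes, classes,
                                            "domain_class"),
                    unit = "DEG", dimension = "domain"),
      dplyr::mutate(enrich_pixels_in_classes(state$dc, classes, "comp_class"),
                    unit = "differential-anchor", dimension = "compartment"),
      dplyr::mutate(enrich_pixels_in_classes(state$dc, classes, "domain_class"),
                    unit = "differential-anchor", dimension = "domain")
    )
    state$classes <- classes
    state$enrichment <- res
    state$deg_ids <- degs
    readr::write_tsv(res, p("enrichment.tsv"), progress = FALSE)
  } else if (name == "profile") {
    need_state(state, "oe1", "balance")
    need_state(state, "deg_ids", "enrich")
    a <- cfg$profile
    g <- state$b1$genome
    picked <- character()
    for (id in state$deg_ids) {
      ok <- tryCatch({
        prof <- gene_interaction_profile(id, state$oe1, state$sim$genes,
                                         flank = a$flank)
        write_bedgraph(prof, p(sprintf("profile_%s_cond1.bedgraph", id)), "oe")
        prof2 <- gene_interaction_profile(id, state$oe2, state$sim$genes,
                                          flank = a$flank)
        write_bedgraph(prof2, p(sprintf("profile_%s_cond2.bedgraph", id)), "oe")
        TRUE
      }, error = function(e) FALSE)
      if (ok) picked <- c(picked, id)
      if (length(picked) >= a$n_genes) break
    }
    state$profiled_genes <- picked
  } else if (name == "report") {
    need_state(state, "comp_cmp", "compartments")
    need_state(state, "dom_cmp", "domains")
    need_state(state, "loop_cmp", "loops")
    need_state(state, "dc", "diffhic")
    need_state(state, "enrichment", "enrich")
    comp_counts <- attr(state$comp_cmp, "summary")
    report <- tibble::tibble(
      metric = c("compartment_bins_changed", "compartment_changed_regions",
                 "domains_cond1", "domains_cond2", "domains_common",
                 "domains_changed", "loops_cond1", "loops_cond2",
                 "loops_common", "loops_specific1", "loops_specific2",
                 "differential_pixels", "differential_regions",
                 "deg_count"),
      value = c(sum(comp_counts$n_bins[comp_counts$class %in% c("A->B", "B->A")]),
                nrow(attr(state$comp_cmp, "changed_regions")),
                nrow(state$dom1), nrow(state$dom2), state$dom_cmp$n_common,
                state$dom_cmp$n_changed1 + state$dom_cmp$n_changed2,
                nrow(state$loops1), nrow(state$loops2),
                nrow(state$loop_cmp$common), nrow(state$loop_cmp$specific1),
                nrow(state$loop_cmp$specific2),
                nrow(state$dc$hits), nrow(state$dc$regions),
                length(state$deg_ids))
    )
    readr::write_tsv(report, p("report.tsv"), progress = FALSE)
    state$report <- report
  }
  state
}

#' Run the full comparative pipeline
#'
#' Chains simulate, balance, compartments, domains, loops, diffhic,
#' enrich, profile and report, writing all artifacts under `out_dir`
#' together with a JSON run log (parameters, seed, package version and an
#' md5 checksum per artifact). A rerun with the same config and seed
#' reproduces byte-identical artifacts.
#'
#' @param cfg A `run_config` list, or a path to a YAML config file.
#' @param out_dir Output directory.
#' @param stages Stages to run, in order (default: all).
#' @return The final state list, invisibly; `state$report` holds the
#'   summary table.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir,
                         stages = pipeline_stages) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  state <- list()
  for (s in stages) {
    message("stage: ", s)
    state <- run_stage(s, cfg, out_dir, state)
  }
  artifacts <- setdiff(list.files(out_dir, recursive = TRUE), "run_log.json")
  log <- list(
    package = "chromarch",
    version = as.character(utils::packageVersion("chromarch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "seed")],
    stages = stages,
    checksums = as.list(tools::md5sum(file.path(out_dir, artifacts)))
  )
  names(log$checksums) <- artifacts
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_log.json"))
  invisible(state)
}
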