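# End-to-end orchestration: classify -> tabulate -> diversity -> curves ->
# CV -> network, with report writers and leave-one-out robustness runs.

resolve_input <- function(input, dialect, scheme, region_col,
                          exclude_assemblages, exclude_characters) {
  classified <- NULL
  if (dialect %in% c("measurements", "classified")) {
    d <- if (is.character(input)) {
      if (dialect == "measurements") read_specimens(input)
      else read_classified(input)
    } else input
    if (!is.null(region_col) && region_col != "region" &&
        region_col %in% names(d)) d$region <- d[[region_col]]
    if (length(exclude_assemblages))
      d <- d[!d$assemblage_id %in% exclude_assemblages, , drop = FALSE]
    if (!nrow(d)) stop("no specimens left after exclusions")
    if (dialect == "measurements") {
      if (length(exclude_characters))
        scheme <- subset_scheme(scheme, exclude_characters)
      classified <- classify_points(d, scheme)
    } else {
      if (length(exclude_characters))
        stop("character exclusion requires the measurements dialect")
      classified <- d
    }
    if (any(!nzchar(classified$region) | is.na(classified$region)))
      stop("empty region label")
    fcs <- lapply(tabulate_classes(classified, by = "region"), as_freq_counts)
  } else if (dialect == "abundances") {
    avs <- if (is.character(input)) read_abundances(input) else input
    if (inherits(avs, "abundance_vector")) avs <- list(all = avs)
    fcs <- lapply(avs, as_freq_counts)
  } else if (dialect == "freqcounts") {
    fcs <- if (is.character(input)) read_freq_counts(input) else input
    if (inherits(fcs, "freq_counts")) fcs <- list(all = fcs)
  } else stop("unknown input dialect: ", dialect)
  list(fcs = fcs, classified = classified, scheme = scheme)
}

#' Run the full diversity pipeline
#'
#' Orchestrates every analysis stage on one input: per-region frequency
#' counts, sample coverage, estimated CV, observed and asymptotic Hill
#' numbers of orders 0-2 with bootstrap standard errors and symmetric 95%
#' intervals, size- and coverage-based rarefaction/extrapolation curves, and
#' (when specimen-level data are available) the class-sharing network
#' summary. All randomness flows from `seed`; two runs with the same config
#' and seed produce identical reports.
#'
#' @param input A file path or in-memory object in the chosen dialect:
#'   `"measurements"` (specimen CSV / data frame), `"classified"`
#'   (specimen_id, assemblage_id, region, class_code), `"abundances"`
#'   (class_code, count, region), or `"freqcounts"` (k, f_k, region).
#' @param dialect Which of the four input forms `input` is.
#' @param scheme Classification scheme for the measurements dialect.
#' @param region_col Name of the region column (default `"region"`).
#' @param B Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @param base_sizes Curve base sizes per order, default
#'   `c(q0 = 300, q1 = 600, q2 = 600)`; a base below an observed n is raised
#'   to n.
#' @param exclude_assemblages,exclude_characters Units to drop before
#'   analysis (robustness runs); character exclusion requires raw
#'   measurements.
#' @param out_dir Optional directory; when given, writes `summary.csv`,
#'   `freq_counts.csv`, `curves.csv`, network files and `run_log.json`.
#' @return An object of class `diversity_report`: list with `summary`
#'   (per-region diversity table), `freq_panel`, `curves`, `network`
#'   (summary list or `NULL`), and `config`.
#' @export
#' @examples
#' rep <- run_diversity(clovis_freq_counts(), dialect = "freqcounts",
#'                      B = 50, seed = 1)
#' rep$summary
run_diversity <- function(input, dialect = c("measurements", "classified",
                                             "abundances", "freqcounts"),
                          scheme = point_scheme(), region_col = "region",
                          B = 200, seed = 1,
                          base_sizes = c(q0 = 300, q1 = 600, q2 = 600),
                          exclude_assemblages = NULL,
                          exclude_characters = NULL,
                          out_dir = NULL) {
  dialect <- match.arg(dialect)
  res <- resolve_input(input, dialect, scheme, region_col,
                       exclude_assemblages, exclude_characters)
  fcs <- res$fcs

  summary_rows <- list(); curve_rows <- list()
  for (rn in names(fcs)) {
    fc <- fcs[[rn]]
    prof <- asymptotic_profile(fc)
    stat_fns <- list(chao1, shannon_asymptotic, simpson_asymptotic)
    se <- unname(vapply(seq_len(3), function(i)
      bootstrap_se(fc, stat_fns[[i]], B = B,
                   seed = seed + i)$se, 1))
    summary_rows[[rn]] <- data.frame(
      row.names = NULL,
      region = rn, n = fc$n, S_obs = fc$S_obs,
      coverage = sample_coverage(fc)$c_hat,
      cv_hat = estimated_cv(fc)$cv_hat,
      q = prof$q, measure = prof$measure,
      observed = prof$observed, asymptote = prof$asymptote,
      se = se,
      ci_low = prof$asymptote - 1.96 * se,
      ci_high = prof$asymptote + 1.96 * se,
      stringsAsFactors = FALSE)
    for (q in 0:2) {
      base <- max(unname(base_sizes[paste0("q", q)]), fc$n)
      for (basis in c("size", "coverage")) {
        cu <- build_curve(fc, q, basis = basis, base_size = base,
                          B = B, seed = seed + 10 + q)
        cu <- cbind(region = rn, cu)
        curve_rows[[length(curve_rows) + 1L]] <- cu
      }
    }
  }
  summary_tab <- do.call(rbind, summary_rows)
  rownames(summary_tab) <- NULL
  curves <- do.call(rbind, curve_rows)
  rownames(curves) <- NULL

  freq_panel <- do.call(rbind, lapply(names(fcs), function(rn)
    data.frame(region = rn, k = fc_k(fcs[[rn]]),
               f_k = as.integer(fcs[[rn]]$f), stringsAsFactors = FALSE)))

  network <- NULL
  if (!is.null(res$classified) &&
      length(unique(res$classified$assemblage_id)) >= 2) {
    profs <- assemblage_profiles(res$classified)
    net <- build_class_network(profs)
    ci <- components_and_isolates(net)
    network <- list(graph = net,
                    density = network_density(net),
                    density_weighted = network_density(net, "weighted"),
                    n_components = ci$n_components,
                    n_isolates = ci$n_isolates,
                    isolates = ci$isolates,
                    main_component_size = length(ci$components[[1]]),
                    cross_region_shared = cross_region_shared_classes(profs))
  }

  config <- list(dialect = dialect, region_col = region_col, B = B,
                 seed = seed, base_sizes = as.list(base_sizes),
                 exclude_assemblages = exclude_assemblages,
                 exclude_characters = exclude_characters,
                 package_version = as.character(utils::packageVersion("paleodiv")))
  report <- structure(list(summary = summary_tab, freq_panel = freq_panel,
                           curves = curves, network = network,
                           config = config),
                      class = "diversity_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity report>\n")
  s <- x$summary
  s$coverage <- round(s$coverage, 3)
  s$cv_hat <- round(s$cv_hat, 3)
  for (col in c("observed", "asymptote", "se", "ci_low", "ci_high"))
    s[[col]] <- round(s[[col]], 1)
  print(s)
  if (!is.null(x$network))
    cat(sprintf(paste0("network: density %.4f, %d components (%d isolates), ",
                       "main component %d nodes, %d cross-region shared classes\n"),
                x$network$density, x$network$n_components,
                x$network$n_isolates, x$network$main_component_size,
                x$network$cross_region_shared))
  invisible(x)
}

#' Write a diversity report bundle to disk
#'
#' Emits `summary.csv` (full precision), `freq_counts.csv`, `curves.csv`,
#' the network edge list/node table/GraphML when a network was built, and a
#' `run_log.json` echoing the configuration and seed so robustness series
#' are auditable.
#'
#' @param report A `diversity_report` from [run_diversity()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$freq_panel, file.path(dir, "freq_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$curves, file.path(dir, "curves.csv"),
                   row.names = FALSE)
  if (!is.null(report$network)) {
    write_edge_list(report$network$graph,
                    file.path(dir, "network_edges.csv"),
                    node_path = file.path(dir, "network_nodes.csv"),
                    graphml_path = file.path(dir, "network.graphml"))
    jsonlite::write_json(report$network[setdiff(names(report$network), "graph")],
                         file.path(dir, "network_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$config, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Leave-one-out robustness series
#'
#' Reruns the pipeline once per excluded unit (each assemblage, or each
#' classification character) and summarizes whether the regional richness
#' ordering holds in every run.
#'
#' @param input,dialect,scheme,... Passed to [run_diversity()]; the
#'   assemblage axis needs specimen-level data and the character axis needs
#'   raw measurements.
#' @param axis `"assemblage"` or `"character"`.
#' @return List with `runs` (named list of `diversity_report`s) and
#'   `summary` (data frame: excluded unit, per-region observed richness and
#'   Chao1).
#' @export
leave_one_out <- function(input, dialect, axis = c("assemblage", "character"),
                          scheme = point_scheme(), ...) {
  axis <- match.arg(axis)
  if (axis == "character") {
    units <- names(scheme)
    runs <- lapply(units, function(u)
      run_diversity(input, dialect, scheme = scheme,
                    exclude_characters = u, ...))
  } else {
    d <- if (is.character(input)) {
      if (dialect == "measurements") read_specimens(input)
      else read_classified(input)
    } else input
    units <- unique(d$assemblage_id)
    runs <- lapply(units, function(u)
      run_diversity(d, dialect, scheme = scheme,
                    exclude_assemblages = u, ...))
  }
  names(runs) <- units
  summ <- do.call(rbind, lapply(units, function(u) {
    s <- runs[[u]]$summary
    s0 <- s[s$q == 0, ]
    data.frame(excluded = u, region = s0$region, n = s0$n,
               S_obs = s0$S_obs, chao1 = s0$asymptote,
               stringsAsFactors = FALSE)
  }))
  list(runs = runs, summary = summ)
}
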