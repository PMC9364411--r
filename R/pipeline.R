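# Orchestration: run the comparative analysis workflow over several
# systems (e.g. R-epimer-bound, S-epimer-bound, apo, endogenous-agonist)
# from one YAML configuration and emit a comparison report.

#' Run the comparative analysis pipeline
#'
#' Executes, per system and as configured: interaction fingerprints over
#' early/late trajectory windows, salt-bridge distance series, residue
#' interaction network + betweenness + filtered shortest paths on the
#' window medoid structure, helix-helix distances, cavity SASA, region
#' helix fraction, and thermodynamic-cycle composition from ensemble
#' files. Deterministic given the config seed; every table carries the
#' config hash, seed and package version.
#'
#' @param config YAML path or an equivalent nested list. Top level:
#'   `seed`, `output_dir` (optional; TSV tables are written there),
#'   `systems` (list; see Details), optional `abfe`.
#' @details Each system supports the fields `name`, `trajectory`
#'   (multi-model PDB path), `ligand` (selection), `ligand_chem`
#'   (template TSV), `numbering_map` (TSV), `saltbridge` (list with
#'   `acid`, `base` selections), `helix_ranges` (named list of
#'   selections), `cavity_residues`, `icl2` (selection for the
#'   helix-fraction region), `windows` (list `early`, `late`: fractions
#'   of the trajectory), `rin` (logical), `paths` (list with `src`,
#'   `dst`, `percentile`). Each `abfe$systems` entry supports `name`,
#'   `complex_ensemble`, `water_ensemble` (TSV paths), `restraint`
#'   (boresch_restraint fields), `temperature`.
#' @return object of class `comparison_report`
#' @export
run_pipeline <- function(config) {
  cfg_file <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_file <- config
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  set.seed(seed)
  prov <- list(
    seed = seed,
    config_hash = if (!is.null(cfg_file)) unname(tools::md5sum(cfg_file))
                  else unname(tools::md5sum(
                    {f <- tempfile(); saveRDS(config, f); f})),
    version = as.character(utils::packageVersion("mdlens")))
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  systems <- list()
  for (sc in config$systems %||% list()) {
    nm <- sc$name %||% paste0("system", length(systems) + 1L)
    res <- tryCatch(
      .run_system(sc, seed),
      error = function(e) stop("pipeline stage failed for system '", nm,
                               "': ", conditionMessage(e), call. = FALSE))
    systems[[nm]] <- res
    if (!is.null(outdir)) .write_system_tables(res, nm, outdir, prov)
  }

  abfe <- list()
  for (ac in (config$abfe %||% list())$systems %||% list()) {
    nm <- ac$name %||% paste0("abfe", length(abfe) + 1L)
    temp <- ac$temperature %||% 300
    comp <- mbar_solve(read_ensemble(ac$complex_ensemble), seed = seed)
    wat <- mbar_solve(read_ensemble(ac$water_ensemble), seed = seed)
    r <- do.call(boresch_restraint, ac$restraint)
    dg_on <- boresch_dg_on(r, temperature = temp)
    abfe[[nm]] <- compose_cycle(-comp$dG_kcal, wat$dG_kcal, as.numeric(dg_on),
                                se = c(comp$se_kcal, wat$se_kcal, 0))
  }

  rep <- structure(list(systems = systems, abfe = abfe, provenance = prov),
                   class = "comparison_report")
  if (!is.null(outdir)) {
    .write_summary(rep, file.path(outdir, "summary.txt"))
  }
  rep
}

.frac_window <- function(nf, frac, side) {
  k <- max(1L, round(nf * frac))
  if (side == "early") seq_len(k) else seq.int(nf - k + 1L, nf)
}

.run_system <- function(sc, seed) {
  t <- parse_multimodel(sc$trajectory)
  if (!is.null(sc$numbering_map))
    t$topology <- apply_numbering(t$topology, sc$numbering_map)
  if (!is.null(sc$ligand_chem))
    attr(t$topology, "ligand_chem") <- read_ligand_template(sc$ligand_chem)
  nf <- n_frames(t)
  out <- list()

  if (!is.null(sc$ligand) && !is.null(attr(t$topology, "ligand_chem")) &&
      length(select_atoms(t$topology, sc$ligand))) {
    wearly <- .frac_window(nf, (sc$windows %||% list())$early %||% 0.2, "early")
    wlate <- .frac_window(nf, (sc$windows %||% list())$late %||% 0.2, "late")
    out$fingerprint_early <- fingerprint(t, sc$ligand, wearly)
    out$fingerprint_late <- fingerprint(t, sc$ligand, wlate)
  } else {
    out$fingerprint_early <- out$fingerprint_late <-
      structure(data.frame(residue = character(), kind = character(),
                           occupancy = numeric()),
                class = c("fingerprint", "data.frame"))
  }

  if (!is.null(sc$saltbridge))
    out$saltbridge <- saltbridge_series(t, sc$saltbridge$acid, sc$saltbridge$base)

  if (isTRUE(sc$rin %||% TRUE)) {
    wmed <- .frac_window(nf, (sc$windows %||% list())$medoid %||% 0.5, "late")
    med <- medoid_structure(t, wmed)
    prot <- med
    het <- prot$atoms$hetero
    if (any(het)) {
      a2 <- prot$atoms[!het, , drop = FALSE]; a2$uid <- NULL
      keepn <- prot$numbering
      prot <- new_structure(a2); prot$numbering <- keepn
    }
    net <- build_rin(prot)
    out$rin <- net
    out$betweenness <- rin_betweenness(net)
    if (!is.null(sc$paths)) {
      ps <- rin_shortest_paths(net, sc$paths$src, sc$paths$dst)
      out$paths <- filter_paths(ps, out$betweenness,
                                sc$paths$percentile %||% 75)
    }
  }

  if (!is.null(sc$helix_ranges)) {
    hr <- sc$helix_ranges
    nms <- names(hr)
    out$helix_distances <- list()
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (j <= i) next
      key <- paste(nms[i], nms[j], sep = "-")
      out$helix_distances[[key]] <- helix_distance(t, hr[[i]], hr[[j]])
    }
  }
  if (!is.null(sc$cavity_residues))
    out$cavity_sasa <- cavity_sasa(t, unlist(sc$cavity_residues))
  if (!is.null(sc$icl2))
    out$helix_fraction <- helix_fraction(t, sc$icl2)
  out
}

.write_system_tables <- function(res, nm, outdir, prov) {
  hdr <- sprintf("# system=%s seed=%d config=%s mdlens=%s",
                 nm, prov$seed, prov$config_hash, prov$version)
  wr <- function(df, f) {
    path <- file.path(outdir, paste0(nm, "_", f, ".tsv"))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  }
  wr(as.data.frame(res$fingerprint_early), "fingerprint_early")
  wr(as.data.frame(res$fingerprint_late), "fingerprint_late")
  if (!is.null(res$saltbridge))
    wr(data.frame(frame = seq_along(res$saltbridge$values),
                  dist = res$saltbridge$values), "saltbridge")
  if (!is.null(res$rin)) wr(res$rin$edges, "rin_edges")
  if (!is.null(res$betweenness)) wr(as.data.frame(res$betweenness), "betweenness")
  if (!is.null(res$cavity_sasa))
    wr(data.frame(frame = seq_along(res$cavity_sasa),
                  sasa = res$cavity_sasa), "cavity_sasa")
  invisible(NULL)
}

.report_metrics <- function(res) {
  m <- c(
    n_contact_residues = length(unique(res$fingerprint_late$residue)),
    mean_saltbridge = if (!is.null(res$saltbridge)) res$saltbridge$mean else NA,
    rin_nodes = if (!is.null(res$rin)) nrow(res$rin$nodes) else NA,
    rin_edges = if (!is.null(res$rin)) nrow(res$rin$edges) else NA,
    max_betweenness = if (!is.null(res$betweenness))
      max(res$betweenness$betweenness) else NA,
    mean_cavity_sasa = if (!is.null(res$cavity_sasa))
      mean(res$cavity_sasa) else NA,
    helix_fraction = if (!is.null(res$helix_fraction))
      res$helix_fraction else NA)
  if (!is.null(res$helix_distances))
    m <- c(m, vapply(res$helix_distances, function(h) h$mean,
                     0)[seq_along(res$helix_distances)])
  m
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d system(s), %d ABFE cycle(s) [seed %d]\n",
              length(x$systems), length(x$abfe), x$provenance$seed))
  for (nm in names(x$systems)) {
    m <- .report_metrics(x$systems[[nm]])
    cat(" ", nm, ":",
        paste(names(m), signif(unlist(m), 5), sep = "=", collapse = " "), "\n")
  }
  for (nm in names(x$abfe))
    cat(sprintf("  %s: dG_bind = %.3f kcal/mol\n", nm, x$abfe[[nm]]$dG_bind))
  invisible(x)
}

.write_summary <- function(rep, file) {
  con <- file(file, "w"); on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(rep)
  invisible(file)
}

#' Compare several pipeline reports
#'
#' Tabulates every scalar metric per system and the pairwise differences
#' (system i minus system j). No significance testing is performed.
#'
#' @param reports either one `comparison_report` (its systems are
#'   compared) or a list of reports whose systems are pooled
#' @return list(values = metric x system data.frame,
#'   deltas = metric x system x system array, antisymmetric)
#' @export
compare_reports <- function(reports) {
  systems <- if (inherits(reports, "comparison_report")) reports$systems
             else do.call(c, lapply(reports, `[[`, "systems"))
  if (length(systems) < 2) stop("need >= 2 systems to compare")
  ms <- lapply(systems, .report_metrics)
  keys <- unique(unlist(lapply(ms, names)))
  for (m in ms)
    if (!identical(sort(names(m)), sort(keys)))
      stop("mismatched metric sets between systems")
  vals <- sapply(ms, function(m) m[keys])
  rownames(vals) <- keys
  k <- ncol(vals)
  deltas <- array(NA_real_, dim = c(length(keys), k, k),
                  dimnames = list(keys, colnames(vals), colnames(vals)))
  for (i in seq_len(k)) for (j in seq_len(k))
    deltas[, i, j] <- vals[, i] - vals[, j]
  list(values = as.data.frame(vals), deltas = deltas)
}
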