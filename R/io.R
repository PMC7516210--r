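#' Read an expression (or trait) matrix with its sample sheet
#'
#' The matrix file is TSV/CSV with entities in rows and sample IDs in
#' columns; the sample sheet is a TSV/CSV with columns `sample_id`,
#' `treatment` (1 or 2), `time`, `replicate`. Matrix columns must match the
#' sample sheet's `sample_id` set exactly. The result is keyed by
#' (entity, treatment, time, replicate) and validated: every
#' (treatment, time) cell must hold at least one replicate, the start time
#' must be present under both treatments, and all values must be numeric.
#'
#' @param matrix_path path to the expression/trait matrix.
#' @param sheet_path path to the sample sheet.
#' @param sep field separator; `NULL` guesses from the file extension
#'   (`.csv` = comma, otherwise tab).
#' @return a `segnet_dataset`: list with `entity_ids`, `times`, `cells`
#'   (per entity, per treatment, per time: numeric replicate vector) and
#'   `design` (the sample sheet).
#' @export
read_expression <- function(matrix_path, sheet_path, sep = NULL) {
  pick_sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  s1 <- if (is.null(sep)) pick_sep(matrix_path) else sep
  s2 <- if (is.null(sep)) pick_sep(sheet_path) else sep
  mat <- utils::read.table(matrix_path, header = TRUE, sep = s1,
                           row.names = 1L, check.names = FALSE)
  sheet <- utils::read.table(sheet_path, header = TRUE, sep = s2,
                             check.names = FALSE,
                             colClasses = c(sample_id = "character"))
  need <- c("sample_id", "treatment", "time", "replicate")
  if (!all(need %in% names(sheet))) {
    stop("read_expression: sample sheet must have columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("read_expression: duplicated sample_id in sample sheet")
  }
  missing_cols <- setdiff(sheet$sample_id, colnames(mat))
  extra_cols <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing_cols)) {
    stop("read_expression: sample sheet names samples absent from matrix: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(extra_cols)) {
    stop("read_expression: matrix columns missing from sample sheet: ",
         paste(extra_cols, collapse = ", "))
  }
  if (!all(sheet$treatment %in% c(1L, 2L))) {
    stop("read_expression: treatment must be 1 or 2")
  }
  M <- as.matrix(mat)
  if (!is.numeric(M)) {
    bad <- which(!vapply(mat, is.numeric, TRUE))[1L]
    stop(sprintf("read_expression: non-numeric value in column '%s'",
                 colnames(mat)[bad]))
  }
  times <- sort(unique(sheet$time))
  if (length(times) < 2L) stop("read_expression: need at least 2 time points")
  for (tr in c(1L, 2L)) {
    for (tm in times) {
      if (!any(sheet$treatment == tr & sheet$time == tm)) {
        stop(sprintf(
          "read_expression: no replicate for treatment %d at time %g", tr, tm))
      }
    }
  }
  ids <- rownames(M)
  cells <- vector("list", length(ids)); names(cells) <- ids
  for (e in ids) {
    by_tr <- list()
    for (tr in c("1", "2")) {
      by_tr[[tr]] <- lapply(times, function(tm) {
        sid <- sheet$sample_id[sheet$treatment == as.integer(tr) &
                                 sheet$time == tm]
        unname(M[e, sid])
      })
    }
    cells[[e]] <- by_tr
  }
  structure(list(entity_ids = ids, times = times, cells = cells,
                 design = sheet),
            class = "segnet_dataset")
}

#' @export
print.segnet_dataset <- function(x, ...) {
  cat(sprintf("segnet_dataset: %d entities, %d time points [%g..%g]\n",
              length(x$entity_ids), length(x$times), min(x$times),
              max(x$times)))
  invisible(x)
}

#' Write a simulated dataset as matrix + sample sheet (+ truth edges)
#'
#' @param truth a `ground_truth` from [simulate_system()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_simulation <- function(truth, dir, prefix = "sim") {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- truth$dataset
  rows <- list(); mat_cols <- list()
  for (tr in c("1", "2")) {
    for (k in seq_along(ds$times)) {
      reps <- length(ds$cells[[1L]][[tr]][[k]])
      for (rp in seq_len(reps)) {
        sid <- sprintf("T%s_t%02d_r%d", tr, k, rp)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, treatment = as.integer(tr),
          time = ds$times[k], replicate = rp)
        mat_cols[[sid]] <- vapply(ds$entity_ids, function(e)
          ds$cells[[e]][[tr]][[k]][rp], numeric(1))
      }
    }
  }
  sheet <- do.call(rbind, rows)
  M <- do.call(cbind, mat_cols)
  rownames(M) <- ds$entity_ids
  mp <- file.path(dir, paste0(prefix, "_expression.tsv"))
  sp <- file.path(dir, paste0(prefix, "_samples.tsv"))
  ep <- file.path(dir, paste0(prefix, "_true_edges.tsv"))
  write_matrix_tsv(M, mp)
  utils::write.table(sheet, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mp, sheet = sp, edges = ep))
}

# TSV writer for a named matrix with an id first column
write_matrix_tsv <- function(M, path, id_col = "id") {
  df <- data.frame(rownames(M), M, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages: read inputs, compute plasticity, cluster genes into modules
#' (optional), infer the ODE network (module- or gene-level), decompose,
#' classify interactions at the requested snapshot time, optionally fit the
#' trait causal layer, and write all declared outputs into the output
#' directory. Every stage is deterministic given the configuration (one
#' master seed governs all randomness).
#'
#' @param config either a path to a YAML file or a named list with entries:
#'   `expression`, `samples` (paths; required), `traits`, `trait_samples`
#'   (paths; optional, both or neither), `out_dir` (required), `level`
#'   (`"module"` or `"gene"`), `l_min`, `l_max` (module-count range),
#'   `lop_order`, `q_order`, `d_max`, `epsilon_frac`, `snapshot_time`
#'   (defaults to the final time), `seed`.
#' @return invisibly, a list with the partition, network fit, snapshot
#'   network and (if requested) trait fits, plus the written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(level = "module", l_min = 1L, l_max = 6L, lop_order = 4L,
                   q_order = 3L, d_max = 5L, epsilon_frac = 0.05,
                   snapshot_time = NULL, seed = 1L, emission = "skellam")
  config <- utils::modifyList(defaults, config)
  for (key in c("expression", "samples", "out_dir")) {
    if (is.null(config[[key]])) stop("run_pipeline: config lacks '", key, "'")
  }
  has_traits <- !is.null(config$traits)
  if (has_traits && is.null(config$trait_samples)) {
    stop("run_pipeline: 'traits' given without 'trait_samples'")
  }
  for (p in c(config$expression, config$samples,
              if (has_traits) c(config$traits, config$trait_samples))) {
    if (!file.exists(p)) stop("run_pipeline: input file not found: ", p)
  }
  if (!config$level %in% c("module", "gene")) {
    stop("run_pipeline: level must be 'module' or 'gene'")
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "",
        file = file.path(out, "pipeline.log"), append = TRUE)
  }
  log_line("seed=%d level=%s lop_order=%s d_max=%d", config$seed,
           config$level, as.character(config$lop_order), config$d_max)

  ds <- read_expression(config$expression, config$samples)
  dtp <- plasticity_matrix(ds)
  write_matrix_tsv(dtp, file.path(out, "plasticity.tsv"), "entity_id")
  log_line("plasticity: %d entities x %d times", nrow(dtp), ncol(dtp))

  partition <- NULL
  if (config$level == "module") {
    partition <- select_module_count(dtp, L_range = config$l_min:config$l_max,
                                     times = ds$times,
                                     lop_order = min(config$lop_order,
                                                     ncol(dtp) - 1L),
                                     emission = config$emission,
                                     seed = config$seed)
    utils::write.table(
      data.frame(gene_id = rownames(dtp), module_id = partition$assignment,
                 max_posterior = apply(partition$posterior, 1L, max)),
      file.path(out, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    level_dtp <- partition$mean_dtp
    rownames(level_dtp) <- paste0("module_", seq_len(partition$L))
    colnames(level_dtp) <- as.character(ds$times)
    log_line("clustering: L=%d (AIC %.2f)", partition$L, partition$aic)
  } else {
    level_dtp <- dtp
  }

  fit <- infer_network(level_dtp, ds$times, d_max = config$d_max,
                       curve_order = min(config$lop_order, ncol(dtp) - 1L),
                       q_order = config$q_order, seed = config$seed)
  snap_t <- if (is.null(config$snapshot_time)) max(ds$times) else
    config$snapshot_time
  net <- build_network(fit$decomps, snap_t,
                       epsilon_frac = config$epsilon_frac)
  utils::write.table(edge_table(net), file.path(out, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_graphml(net, file.path(out, "network.graphml"))
  log_line("network: %d edges at t=%g", nrow(net$edges), snap_t)
  for (id in names(fit$fits)) {
    f <- fit$fits[[id]]
    jsonlite::write_json(
      list(target = id, regulators = f$regulators,
           theta_i = f$theta_i, theta_dep = f$theta_dep, sse = f$sse),
      file.path(out, paste0("fit_", id, ".json")), auto_unbox = TRUE,
      digits = NA)
  }

  trait_fits <- NULL
  if (has_traits) {
    tds <- read_expression(config$traits, config$trait_samples)
    dpp <- plasticity_matrix(tds)
    gene_curves <- fit$curves
    trait_fits <- fit_trait_system(dpp, gene_curves, times = tds$times,
                                   d_max = config$d_max,
                                   q_order = config$q_order,
                                   curve_order = min(config$lop_order,
                                                     ncol(dpp) - 1L),
                                   seed = config$seed)
    utils::write.table(causal_edge_table(trait_fits, snap_t),
                       file.path(out, "causal_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_line("traits: %d fitted", length(trait_fits))
  }
  invisible(list(dataset = ds, dtp = dtp, partition = partition,
                 fit = fit, network = net, trait_fits = trait_fits,
                 out_dir = out))
}
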