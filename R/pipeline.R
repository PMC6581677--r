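# Orchestration: one config in, a directory of report tables out.
# Stage order: load/simulate -> associations -> dominance -> metrics ->
# homophily tests -> centrality models -> transfer analysis.

#' Build a pipeline run configuration
#'
#' Every stochastic stage derives its seed from `seed`, and the whole
#' configuration is persisted verbatim into the output directory, so a
#' run is reproducible from its own report bundle.
#'
#' @param scenario a [herd_scenario()] to simulate from, or `NULL` when
#'   `input` paths are given.
#' @param input `NULL`, or a named list/vector with paths `roster`,
#'   `scans`, `agonistic`, `manifest`.
#' @param exclusion_days post-change scan exclusion window (default 7:
#'   scoring starts on day 8).
#' @param familiarity_threshold co-residence days for familiarity
#'   (default 90, strict).
#' @param n_perm_mantel,n_perm_model,n_perm_cor permutation counts for
#'   the Mantel tests, the node-label model permutations and the
#'   stability correlation test.
#' @param correction_mode group-size correction, `"residual"` or
#'   `"literal"`.
#' @param combine_method p-value combination across compositions,
#'   `"fisher"` or `"stouffer"`.
#' @param mantel_sided,stability_sided explicit sidedness of the homophily
#'   Mantel tests and of the stability tests (recorded in every output
#'   row).
#' @param delta_cut AICc best-model cut, default 2.
#' @param seed master integer seed.
#' @return A `run_config` object.
#' @export
run_config <- function(scenario = herd_scenario(), input = NULL,
                       exclusion_days = 7, familiarity_threshold = 90,
                       n_perm_mantel = 1000, n_perm_model = 1000,
                       n_perm_cor = 1000,
                       correction_mode = c("residual", "literal"),
                       combine_method = c("fisher", "stouffer"),
                       mantel_sided = "two", stability_sided = "two",
                       delta_cut = 2, seed = 1L) {
  if (min(n_perm_mantel, n_perm_model, n_perm_cor) < 100)
    .stop("permutation counts below 100 are refused: the p-value resolution would be meaningless")
  structure(list(scenario = scenario, input = input,
                 exclusion_days = exclusion_days,
                 familiarity_threshold = familiarity_threshold,
                 n_perm_mantel = n_perm_mantel,
                 n_perm_model = n_perm_model, n_perm_cor = n_perm_cor,
                 correction_mode = match.arg(correction_mode),
                 combine_method = match.arg(combine_method),
                 mantel_sided = mantel_sided,
                 stability_sided = stability_sided,
                 delta_cut = delta_cut, seed = as.integer(seed)),
            class = "run_config")
}

.write_df <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured input (or synthetic scenario)
#' and writes the report bundle to `output_dir`: per-composition
#' association matrices and edge lists, dominance score tables, the
#' metric table with group-size-corrected centralities, homophily Mantel
#' results with combined global p-values, the centrality and
#' centrality-difference model tables (AICc model sets, RVIs, node-label
#' permutation p-values), the transfer records with per-individual
#' deltas, a verbatim copy of the configuration and a manifest with an
#' MD5 checksum per file.  Identical configurations produce byte-identical
#' bundles.
#'
#' @param config a [run_config()].
#' @param output_dir directory for the report bundle (created).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  # --- stage: data -------------------------------------------------------
  herd <- if (!is.null(config$input)) {
    inp <- config$input
    load_tables(inp[["roster"]], inp[["scans"]], inp[["agonistic"]],
                inp[["manifest"]])
  } else {
    generate_herd(config$scenario, config$seed)
  }
  write_tables(herd, file.path(output_dir, "data"))
  comps <- herd$compositions

  # --- stage: associations + dominance ----------------------------------
  assoc <- list(); mds <- list()
  dir.create(file.path(output_dir, "networks"), showWarnings = FALSE)
  for (k in seq_len(nrow(comps))) {
    cid <- comps$composition_id[k]
    co <- .as_composition(comps[k, , drop = FALSE])
    a <- build_association_matrix(herd$scans, co,
                                  exclusion_days = config$exclusion_days)
    assoc[[cid]] <- a
    write_association_csv(a, file.path(output_dir, "networks",
                                       paste0(cid, "_association.csv")))
    write_edge_list(a, file.path(output_dir, "networks",
                                 paste0(cid, "_edges.csv")))
    m <- compute_mds(agonistic_matrix(herd$events, co))
    mds[[cid]] <- m
    write_mds_csv(m, file.path(output_dir, "networks",
                               paste0(cid, "_dominance.csv")))
    say("composition %s: N = %d, %d scans used, exclusion %d days, %d agonistic events",
        cid, length(co$members), a$n_scans_used, config$exclusion_days,
        comps$n_agonistic[k])
  }

  # --- stage: metric table ----------------------------------------------
  metrics <- build_metric_table(herd, assoc, mds,
                                exclusion_days = config$exclusion_days,
                                familiarity_threshold =
                                  config$familiarity_threshold)
  metrics <- correct_for_group_size(metrics, mode = config$correction_mode)
  .write_df(metrics, output_dir, "metrics.csv")

  # --- stage: homophily --------------------------------------------------
  homophily <- .stage_homophily(herd, assoc, mds, config)
  .write_df(homophily, output_dir, "homophily.csv")

  # --- stage: centrality models -----------------------------------------
  model_out <- list()
  sex_ok <- length(unique(metrics$sex[!is.na(metrics$sex)])) >= 2L
  cent_terms <- c("age", if (sex_ok) "sex", "dominance", "familiarity")
  for (resp in c("eigenvector_corrected", "strength_corrected")) {
    tab <- metrics[complete.cases(metrics[c(resp, cent_terms,
                                            "individual_id",
                                            "composition_id")]), ]
    model_out[[resp]] <- .stage_model(resp, cent_terms, tab, config,
                                      seed_offset = 10L +
                                        match(resp,
                                              c("eigenvector_corrected",
                                                "strength_corrected")))
    .write_df(model_out[[resp]]$terms, output_dir,
              paste0("model_", sub("_corrected", "", resp), ".csv"))
    .write_df(model_out[[resp]]$inference$models, output_dir,
              paste0("model_set_", sub("_corrected", "", resp), ".csv"))
  }

  # --- stage: transfers --------------------------------------------------
  tr <- .stage_transfers(herd, assoc, metrics, config)
  if (length(tr$records)) {
    .write_df(tr$transfers, output_dir, "transfers.csv")
    .write_df(tr$deltas, output_dir, "deltas.csv")
  }
  delta_models <- list()
  if (!is.null(tr$delta_table) && nrow(tr$delta_table) >= 10L) {
    # sex deliberately excluded from the difference models
    dterms <- c("age", "familiarity_new", "d_rank", "n_transferred")
    dterms <- dterms[vapply(dterms, function(tm)
      sd(tr$delta_table[[tm]], na.rm = TRUE) > 0, logical(1))]
    for (resp in c("d_eigenvector", "d_strength")) {
      tab <- tr$delta_table[complete.cases(tr$delta_table[c(resp, dterms)]), ]
      delta_models[[resp]] <- .stage_model(resp, dterms, tab, config,
                                           seed_offset = 20L +
                                             match(resp, c("d_eigenvector",
                                                           "d_strength")))
      .write_df(delta_models[[resp]]$terms, output_dir,
                paste0("model_", resp, ".csv"))
      .write_df(delta_models[[resp]]$inference$models, output_dir,
                paste0("model_set_", resp, ".csv"))
    }
  }
  stability <- NULL
  if (length(tr$records) >= 3L) {
    n_tr <- vapply(tr$records, `[[`, integer(1), "n_transferred")
    if (sd(n_tr) > 0) {
      stability <- stability_vs_transfers(tr$records,
                                          sided = config$stability_sided,
                                          n_perm = config$n_perm_cor,
                                          seed = config$seed + 30L)
      .write_df(data.frame(rho = stability$estimate, p = stability$p,
                           n_perm = stability$n_perm,
                           sided = stability$sided,
                           n_records = length(tr$records)),
                output_dir, "stability.csv")
    }
  }

  # --- manifest ----------------------------------------------------------
  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(.config_as_list(config), cfg_path)
  files <- sort(setdiff(list.files(output_dir, recursive = TRUE),
                        "manifest.csv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(output_dir, files))),
    stringsAsFactors = FALSE)
  .write_df(manifest, output_dir, "manifest.csv")

  invisible(list(herd = herd, associations = assoc, dominance = mds,
                 metrics = metrics, homophily = homophily,
                 models = model_out, transfers = tr,
                 delta_models = delta_models, stability = stability,
                 manifest = manifest, output_dir = output_dir))
}

.config_as_list <- function(config) {
  out <- unclass(config)
  out$scenario <- if (is.null(out$scenario)) NULL else {
    sc <- unclass(out$scenario)
    sc$origin <- format(sc$origin, "%Y-%m-%d")
    sc$sexes <- as.list(sc$sexes)
    sc
  }
  out$input <- if (is.null(out$input)) NULL else as.list(out$input)
  out
}

.stage_homophily <- function(herd, assoc, mds, config) {
  rows <- list()
  seed_k <- 0L
  for (k in seq_len(nrow(herd$compositions))) {
    cid <- herd$compositions$composition_id[k]
    co <- .as_composition(herd$compositions[k, , drop = FALSE])
    if (length(co$members) < 3L) next
    a <- assoc[[cid]]
    if (all(a$counts == 0)) next
    ind <- herd$individuals
    age <- setNames(compute_age(ind$birth_date[match(co$members, ind$id)],
                                co$start_date), co$members)
    rank <- setNames(mds[[cid]]$scores$rank[match(co$members,
                                                  mds[[cid]]$scores$id)],
                     co$members)
    sex <- setNames(as.character(ind$sex[match(co$members, ind$id)]),
                    co$members)
    pairs <- list(
      `DyaAsso-dominance` = list(a$counts, difference_matrix(rank, "rank")),
      `DyaAsso-age` = list(a$counts, difference_matrix(age, "age")),
      `Dominance-age` = list(difference_matrix(rank, "rank"),
                             difference_matrix(age, "age")))
    if (length(unique(sex)) >= 2L)
      pairs[["DyaAsso-sex"]] <- list(a$counts,
                                     difference_matrix(sex, "sex"))
    for (nm in names(pairs)) {
      seed_k <- seed_k + 1L
      X <- pairs[[nm]][[1L]]; Y <- pairs[[nm]][[2L]]
      res <- tryCatch(
        mantel_test(X, Y, sided = config$mantel_sided,
                    n_perm = config$n_perm_mantel,
                    seed = config$seed + 100L + seed_k),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        composition_id = cid, matrix_pair = nm, r = res$r, p = res$p,
        n_perm = res$n_perm, sided = res$sided,
        exhaustive = res$exhaustive,
        seed = res$seed %||% NA_integer_, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(data.frame())
  for (nm in unique(tab$matrix_pair)) {
    sub <- tab[tab$matrix_pair == nm, ]
    if (nrow(sub) < 2L) next
    tab <- rbind(tab, data.frame(
      composition_id = "global", matrix_pair = nm,
      r = mean(abs(sub$r)), p = combine_pvalues(sub$p,
                                                config$combine_method),
      n_perm = NA_integer_, sided = config$mantel_sided,
      exhaustive = NA, seed = NA_integer_, stringsAsFactors = FALSE))
  }
  rownames(tab) <- NULL
  tab
}

.stage_model <- function(response, terms, tab, config, seed_offset) {
  spec <- model_spec(response, terms)
  inference <- all_subsets_inference(spec, tab,
                                     delta_cut = config$delta_cut)
  perms <- node_label_permutation(spec, tab,
                                  n_perm = config$n_perm_model,
                                  seed = config$seed + seed_offset)
  # estimates/SE/z from the full-candidate fit; permutation p and RVI merged in
  full <- inference$fits[[length(inference$fits)]]$coefficients
  terms_tab <- merge(full, perms[c("term", "p_perm_left", "p_perm_right")],
                     by = "term", all.x = TRUE, sort = FALSE)
  terms_tab <- terms_tab[match(full$term, terms_tab$term), ]
  # RVI is defined per candidate term; dummy columns inherit their term's
  rvi_of <- function(col) {
    hit <- vapply(names(inference$rvi), function(tm)
      startsWith(col, tm), logical(1))
    if (any(hit)) unname(inference$rvi[which(hit)[1L]]) else NA_real_
  }
  terms_tab$rvi <- vapply(terms_tab$term, rvi_of, numeric(1))
  terms_tab <- terms_tab[, c("term", "estimate", "std_error", "z_value",
                             "p_perm_left", "p_perm_right", "rvi")]
  names(terms_tab)[5:6] <- c("pperm_left", "pperm_right")
  list(terms = terms_tab, inference = inference, perms = perms)
}

.stage_transfers <- function(herd, assoc, metrics, config) {
  comps <- herd$compositions
  records <- list(); delta_rows <- list()
  for (g in unique(comps$group)) {
    sub <- comps[comps$group == g, , drop = FALSE]
    sub <- sub[order(sub$start_date), , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (k in seq_len(nrow(sub) - 1L)) {
      cb <- sub[k, , drop = FALSE]; ca <- sub[k + 1L, , drop = FALSE]
      rec <- tryCatch(build_transfer_record(
        cb, ca, assoc[[cb$composition_id]], assoc[[ca$composition_id]],
        metrics[metrics$composition_id == cb$composition_id, ],
        metrics[metrics$composition_id == ca$composition_id, ],
        sided = config$stability_sided, n_perm = config$n_perm_mantel,
        seed = config$seed + 200L + length(records)),
        error = function(e) { .warn("transfer %s -> %s skipped: %s",
                                    cb$composition_id, ca$composition_id,
                                    conditionMessage(e)); NULL })
      if (is.null(rec)) next
      records[[length(records) + 1L]] <- rec
      d <- rec$deltas
      d$before_id <- rec$before; d$after_id <- rec$after
      d$n_transferred <- rec$n_transferred
      ind <- herd$individuals
      d$age <- compute_age(ind$birth_date[match(d$individual_id, ind$id)],
                           ca$start_date)
      d$composition_id <- paste(rec$before, rec$after, sep = "->")
      delta_rows[[length(delta_rows) + 1L]] <- d
    }
  }
  if (!length(records))
    return(list(records = list(), transfers = NULL, deltas = NULL,
                delta_table = NULL))
  transfers <- do.call(rbind, lapply(records, function(x) data.frame(
    before_id = x$before, after_id = x$after,
    n_transferred = x$n_transferred, enclosure_only = x$enclosure_only,
    mantel_r = x$mantel$r, mantel_p = x$mantel$p,
    n_shared = length(x$shared_members), stringsAsFactors = FALSE)))
  delta_table <- do.call(rbind, delta_rows)
  deltas <- delta_table[, c("individual_id", "before_id", "after_id",
                            setdiff(names(delta_table),
                                    c("individual_id", "before_id",
                                      "after_id", "age", "composition_id",
                                      "n_transferred")))]
  list(records = records, transfers = transfers, deltas = deltas,
       delta_table = delta_table)
}
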