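# End-to-end orchestration: construct -> junction calling -> null model ->
# cohort summaries and young-vs-old comparisons -> efficiency, with
# plain-text outputs and a machine-readable manifest.

#' Assemble and validate a pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the manifest and driving any simulation.
#' @param construct either `list(fasta = , annotation = )` paths, or `NULL`
#'   to simulate the bundled default construct.
#' @param cohorts either a list of `list(name, reads, tissue, age)` entries
#'   (`reads` = junction FASTA path; `age` in `"young"`/`"old"`), or `NULL`
#'   to simulate the default study design.
#' @param facs optional FACS TSV path; `NULL` simulates one when cohorts are
#'   simulated.
#' @param params a [call_params()]; its window is filled in from the
#'   construct.
#' @param k_min minimum microhomology counted in the null-excess test.
#' @param dedupe apply the per-reaction uniqueness rule.
#' @return validated config list of class `nhej_config`.
#' @export
nhej_config <- function(out_dir, seed = 1L, construct = NULL, cohorts = NULL,
                        facs = NULL, params = call_params(), k_min = 1L,
                        dedupe = TRUE) {
  if (missing(out_dir) || is.null(out_dir)) {
    .stop_nhej("config error: `out_dir` is required", "nhej_config_error")
  }
  if (!is.null(construct)) {
    for (key in c("fasta", "annotation")) {
      if (is.null(construct[[key]])) {
        .stop_nhej(sprintf("config error: construct$%s is missing", key),
                   "nhej_config_error")
      }
      if (!file.exists(construct[[key]])) {
        .stop_nhej(sprintf("config error: construct$%s path does not exist: %s",
                           key, construct[[key]]), "nhej_config_error")
      }
    }
  }
  if (!is.null(cohorts)) {
    for (co in cohorts) {
      if (is.null(co$name) || is.null(co$reads)) {
        .stop_nhej("config error: every cohort needs `name` and `reads`",
                   "nhej_config_error")
      }
      if (!file.exists(co$reads)) {
        .stop_nhej(sprintf("config error: reads path for cohort '%s' does not exist: %s",
                           co$name, co$reads), "nhej_config_error")
      }
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 construct = construct, cohorts = cohorts, facs = facs,
                 params = params, k_min = as.integer(k_min),
                 dedupe = isTRUE(dedupe)),
            class = "nhej_config")
}

#' Run the full junction-analysis pipeline
#'
#' Produces, under `config$out_dir`: `events.tsv` (all retained events, with
#' cohort columns), `rejects.tsv`, `summary.tsv` (one row per cohort),
#' `comparisons.tsv` (young vs old per tissue, six metrics each),
#' `mh_excess.tsv` (per-cohort observed-vs-null microhomology test),
#' `null_probs.tsv`, `null_summary.json`, `efficiency.tsv` and
#' `manifest.json`. Deterministic under a fixed seed: two runs with the same
#' config yield byte-identical TSVs.
#'
#' @param config an [nhej_config()] (or a list/JSON path accepted by it).
#' @return object of class `nhej_run` holding every table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(nhej_config, jsonlite::fromJSON(config,
                                                      simplifyVector = FALSE))
  }
  if (!inherits(config, "nhej_config")) {
    config <- do.call(nhej_config, config)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  .with_seed(config$seed, {
    simulated <- is.null(config$cohorts)

    if (simulated) {
      study <- simulate_study(seed = NULL) # runs on the seeded stream
      construct <- study$construct
      cutref <- study$cutref
      window <- study$window
      cohort_reads <- split(study$reads,
                            paste(study$reads$tissue, study$reads$age,
                                  sep = "_"))
      cohort_meta <- unique(study$reads[, c("tissue", "age")])
      cohort_meta$name <- paste(cohort_meta$tissue, cohort_meta$age,
                                sep = "_")
      facs <- study$facs
      write_construct(construct, out("construct.fa"),
                      out("construct_annotation.json"))
      write_reads_fasta(study$reads, out("reads.fa"))
      .write_tsv(study$truth, out("truth.tsv"))
    } else {
      if (is.null(config$construct)) {
        .stop_nhej("config error: cohorts from files require a construct",
                   "nhej_config_error")
      }
      construct <- load_construct(config$construct$fasta,
                                  config$construct$annotation)
      cutref <- derive_cut_reference(construct)
      window <- detection_window(construct, cutref)
      cohort_reads <- list()
      meta <- list()
      for (co in config$cohorts) {
        rd <- read_junctions(co$reads)
        rd$tissue <- if (is.null(co$tissue)) co$name else co$tissue
        rd$age <- if (is.null(co$age)) NA_character_ else co$age
        cohort_reads[[co$name]] <- rd
        meta[[co$name]] <- data.frame(
          tissue = rd$tissue[1L], age = rd$age[1L], name = co$name,
          stringsAsFactors = FALSE)
      }
      cohort_meta <- do.call(rbind, meta)
      facs <- if (is.null(config$facs)) NULL else read_facs(config$facs)
    }

    params <- config$params
    params$window <- window

    # stage: junction calling
    events <- list()
    rejects <- list()
    for (nm in names(cohort_reads)) {
      res <- tryCatch(
        batch_analyze(cohort_reads[[nm]], cutref, params,
                      dedupe = config$dedupe),
        error = function(e) {
          .stop_nhej(sprintf("stage junction_caller failed on cohort '%s': %s",
                             nm, conditionMessage(e)), "nhej_pipeline_error")
        })
      if (nrow(res$events)) {
        res$events$cohort <- nm
        res$events$tissue <- cohort_reads[[nm]]$tissue[1L]
        res$events$age <- cohort_reads[[nm]]$age[1L]
      }
      events[[nm]] <- res$events
      if (nrow(res$rejects)) {
        res$rejects$cohort <- nm
        rejects[[nm]] <- res$rejects
      }
    }
    all_events <- do.call(rbind, c(events, list(make.row.names = FALSE)))
    all_rejects <- if (length(rejects)) {
      do.call(rbind, c(rejects, list(make.row.names = FALSE)))
    } else {
      data.frame(read_id = character(0), reason = character(0),
                 cohort = character(0))
    }

    # stage: null model
    null <- random_joining_distribution(cutref, window)
    mh_cap <- null$max_mh

    # stage: cohort summaries + null-excess tests
    summaries <- list()
    excess <- list()
    for (nm in names(events)) {
      ev <- events[[nm]][!events[[nm]]$ad_retained, , drop = FALSE]
      if (nrow(ev) == 0L) next
      summaries[[nm]] <- as.data.frame(
        summarize_cohort(ev, params, mh_cap = mh_cap, cohort = nm))
      tt <- mh_excess_test(ev, null, k_min = config$k_min)
      excess[[nm]] <- data.frame(
        cohort = nm, k_min = config$k_min, observed = tt$estimate1,
        expected = tt$estimate2, statistic = tt$statistic,
        p_value = tt$p_value, stringsAsFactors = FALSE)
    }
    summary_df <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
    excess_df <- do.call(rbind, c(excess, list(make.row.names = FALSE)))

    # stage: young-vs-old comparisons per tissue
    comparisons <- list()
    tissues <- unique(cohort_meta$tissue)
    for (tissue in tissues) {
      ynm <- cohort_meta$name[cohort_meta$tissue == tissue &
                                cohort_meta$age == "young"]
      onm <- cohort_meta$name[cohort_meta$tissue == tissue &
                                cohort_meta$age == "old"]
      if (length(ynm) != 1L || length(onm) != 1L) next
      cmp <- compare_cohorts(events[[ynm]], events[[onm]], params,
                             mh_cap = mh_cap)
      cmp$tissue <- tissue
      comparisons[[tissue]] <- cmp
    }
    comparison_df <- if (length(comparisons)) {
      do.call(rbind, c(comparisons, list(make.row.names = FALSE)))
    } else NULL

    # stage: efficiency
    efficiency_df <- NULL
    if (!is.null(facs)) {
      facs$efficiency <- nhej_efficiency(facs)
      if (!is.null(facs$tissue) && !is.null(facs$age)) {
        groups <- split(facs, paste(facs$tissue, facs$age, sep = "_"))
        eff <- lapply(groups, function(g) {
          es <- efficiency_summary(g$efficiency)
          data.frame(tissue = g$tissue[1L], age = g$age[1L],
                     mean_efficiency = es$mean, sem = es$sem, n = es$n,
                     stringsAsFactors = FALSE)
        })
        efficiency_df <- do.call(rbind, c(eff, list(make.row.names = FALSE)))
        fold <- lapply(split(efficiency_df, efficiency_df$tissue),
                       function(g) {
          if (!all(c("young", "old") %in% g$age)) return(NULL)
          data.frame(tissue = g$tissue[1L],
                     fold_decline = g$mean_efficiency[g$age == "young"] /
                       g$mean_efficiency[g$age == "old"],
                     stringsAsFactors = FALSE)
        })
        fold_df <- do.call(rbind, c(fold, list(make.row.names = FALSE)))
        efficiency_df <- merge(efficiency_df, fold_df, by = "tissue",
                               all.x = TRUE, sort = TRUE)
      } else {
        efficiency_df <- as.data.frame(facs)
      }
    }

    # write outputs
    .write_tsv(all_events, out("events.tsv"))
    .write_tsv(all_rejects, out("rejects.tsv"))
    .write_tsv(summary_df, out("summary.tsv"))
    if (!is.null(comparison_df)) .write_tsv(comparison_df,
                                            out("comparisons.tsv"))
    .write_tsv(excess_df, out("mh_excess.tsv"))
    .write_tsv(data.frame(mh = as.integer(names(null$probs)),
                          prob = unname(null$probs),
                          p_mh_ge = c(NA, unname(null$p_mh_ge))),
               out("null_probs.tsv"))
    jsonlite::write_json(
      list(n_pairs = null$n_pairs, max_mh = null$max_mh,
           p_mh_ge_1 = if (null$max_mh >= 1L) unname(null$p_mh_ge[["1"]])
                       else 0,
           window = unclass(window)),
      out("null_summary.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(efficiency_df)) .write_tsv(efficiency_df,
                                            out("efficiency.tsv"))
    jsonlite::write_json(
      list(package = "nhejscan",
           version = as.character(utils::packageVersion("nhejscan")),
           r_version = paste(R.version$major, R.version$minor, sep = "."),
           seed = config$seed, simulated = simulated,
           params = list(mmej_min = params$mmej_min,
                         mmej_max = params$mmej_max,
                         max_mismatch = params$max_mismatch,
                         dedupe = config$dedupe, k_min = config$k_min,
                         window = unclass(window)),
           cohorts = names(cohort_reads)),
      out("manifest.json"), auto_unbox = TRUE, digits = NA)

    structure(list(out_dir = config$out_dir, seed = config$seed,
                   construct = construct, window = window, null = null,
                   events = all_events, rejects = all_rejects,
                   summary = summary_df, comparisons = comparison_df,
                   mh_excess = excess_df, efficiency = efficiency_df),
              class = "nhej_run")
  })
}

#' @export
print.nhej_run <- function(x, ...) {
  cat(sprintf("NHEJ junction-analysis run (seed %d) -> %s\n", x$seed,
              x$out_dir))
  cat(sprintf("  %d events across %d cohorts; %d rejects\n",
              nrow(x$events), length(unique(x$events$cohort)),
              nrow(x$rejects)))
  cat(sprintf("  null: P(MH >= 1) = %.3f over %d pairs, longest MH %d bp\n",
              if (x$null$max_mh >= 1L) x$null$p_mh_ge[["1"]] else 0,
              x$null$n_pairs, x$null$max_mh))
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons[x$comparisons$significant, , drop = FALSE]
    cat(sprintf("  %d of %d young-vs-old metric tests significant at 0.05\n",
                nrow(sig), nrow(x$comparisons)))
  }
  invisible(x)
}

#' @export
summary.nhej_run <- function(object, ...) {
  cat("Cohort summaries:\n")
  print(object$summary, digits = 3)
  cat("\nMicrohomology usage vs random-joining null:\n")
  print(object$mh_excess, digits = 3)
  if (!is.null(object$efficiency)) {
    cat("\nNHEJ efficiency (GFP+/DsRed+):\n")
    print(object$efficiency, digits = 3)
  }
  invisible(object)
}
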