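# ---------------------------------------------------------------------------
# Orchestration: run all five analyses over a multi-treatment collection of
# OTU tables and emit a consolidated, reproducible report.
# ---------------------------------------------------------------------------

#' Run the full neutrality-analysis pipeline
#'
#' For every treatment: per-sample Hubbell neutrality tests with the
#' treatment passing rate, the stochasticity analysis (SR / NSR), and the
#' multi-site neutral model fit with its P_M / P_L tests. For every ordered
#' treatment pair (or the same-set scheme): a Sloan near-neutral fit with
#' species classification. Optionally, a per-sample power analysis (PNT)
#' against the IF and PC non-neutral generators. A failure in any stage is
#' logged and isolated to its treatment; the pipeline continues.
#'
#' All randomness flows from `seed` via fixed per-stage offsets, so a rerun
#' with the same inputs and seed reproduces the report byte for byte.
#' No rarefaction is performed at any stage.
#'
#' @param treatments Named list of [community_matrix()] objects or TSV file
#'   paths (one entry per treatment).
#' @param out_dir Optional output directory; when given, writes
#'   `report.json` plus `hnm.tsv`, `nsr.tsv`, `msn.tsv`, `sloan.tsv` and
#'   `pnt.tsv`.
#' @param min_reads Per-sample read filter applied before testing (default
#'   100; set to 1 to disable).
#' @param run Character vector of stages to run; any subset of
#'   `c("hnm", "nsr", "msn", "sloan", "pnt")`.
#' @param n_sim Neutral replicates per Hubbell test (default 200).
#' @param n_null Null randomizations for SR / NSR (default 200).
#' @param n_gibbs,burn_in Gibbs sampler lengths for the multi-site model.
#' @param msn_n_sim Simulated datasets for the P_M / P_L tests.
#' @param pnt_effect Non-neutral effect size used by the power analysis.
#' @param pnt_n_datasets,pnt_n_sim Power-analysis dataset and per-test
#'   replicate counts.
#' @param alpha Rejection threshold shared by all tests (default 0.05).
#' @param pairs Optional two-column matrix or data frame of treatment-name
#'   pairs (source, destination) for the Sloan stage; defaults to all
#'   ordered pairs.
#' @param sloan_same_set Also fit each treatment against itself (the
#'   same-set scheme)?
#' @param seed Integer master seed (default 1).
#' @return A report list (class `untbx_report`) with one tibble per stage,
#'   invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(treatments, out_dir = NULL, min_reads = 100,
                         run = c("hnm", "nsr", "msn", "sloan", "pnt"),
                         n_sim = 200, n_null = 200,
                         n_gibbs = 2000, burn_in = 1000, msn_n_sim = 100,
                         pnt_effect = 2, pnt_n_datasets = 20, pnt_n_sim = 50,
                         alpha = 0.05, pairs = NULL, sloan_same_set = FALSE,
                         seed = 1) {
  if (is.null(names(treatments)) || any(names(treatments) == "")) {
    abort("`treatments` must be a named list.")
  }
  run <- match.arg(run, several.ok = TRUE)
  loaded <- list()
  for (nm in names(treatments)) {
    x <- treatments[[nm]]
    cm <- if (is.character(x)) read_otu_table(x) else as_count_matrix(x)
    cm <- tryCatch(
      filter_min_reads(cm, min_reads),
      error = function(e) {
        inform(sprintf("treatment '%s' skipped: %s", nm, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(cm)) loaded[[nm]] <- cm
  }
  if (length(loaded) == 0) abort("no treatment survived the read filter.")

  report <- list(
    schema = "untbx_report/1",
    seed = seed,
    alpha = alpha,
    min_reads = min_reads,
    treatments = names(loaded),
    skipped = setdiff(names(treatments), names(loaded))
  )
  stage <- function(name, offset, code) {
    tryCatch(
      with_seed(child_seed(seed, offset), code),
      error = function(e) {
        inform(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
        NULL
      }
    )
  }

  if ("hnm" %in% run) {
    report$hnm <- purrr::imap_dfr(loaded, function(cm, nm) {
      stage(paste0("hnm/", nm), 1, {
        rows <- purrr::map_dfr(colnames(cm), function(sid) {
          sad <- extract_sad(cm, sid)
          tst <- suppressWarnings(
            hnm_neutrality_test(sad, n_sim = n_sim, alpha = alpha)
          )
          tibble::tibble(
            treatment = nm, sample = sid, J = sad$J, S = sad$S,
            theta = tst$fit$theta, m = tst$fit$m,
            pseudo_p = tst$pseudo_p, verdict = tst$verdict
          )
        })
        rows$passing_rate <- mean(rows$pseudo_p > alpha)
        rows
      })
    })
  }
  if ("nsr" %in% run) {
    report$nsr <- purrr::imap_dfr(loaded, function(cm, nm) {
      stage(paste0("nsr/", nm), 2, {
        if (ncol(cm) < 2) {
          inform(sprintf("treatment '%s': fewer than 2 samples, NSR skipped.", nm))
          return(tibble::tibble())
        }
        res <- nsr(cm, n_null = n_null)
        tibble::tibble(
          treatment = nm, n_pairs = res$n_pairs,
          mean_pairwise_similarity = res$mean_pairwise_similarity,
          SR = res$SR, NSR = res$NSR
        )
      })
    })
  }
  if ("msn" %in% run) {
    report$msn <- purrr::imap_dfr(loaded, function(cm, nm) {
      stage(paste0("msn/", nm), 3, {
        fit <- suppressWarnings(fit_msn(cm, n_gibbs = n_gibbs, burn_in = burn_in))
        tst <- msn_neutrality_test(fit, cm, n_sim = msn_n_sim)
        tibble::tibble(
          treatment = nm, sample = names(tst$P_L),
          theta = fit$theta, I = unname(fit$I), m = unname(fit$m),
          P_M = tst$P_M, P_L = unname(tst$P_L),
          pass_M = tst$P_M > alpha, pass_L = unname(tst$P_L) > alpha
        )
      })
    })
  }
  if ("sloan" %in% run) {
    if (is.null(pairs)) {
      nms <- names(loaded)
      pairs <- expand.grid(source = nms, dest = nms, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$source != pairs$dest, , drop = FALSE]
    }
    pairs <- as.data.frame(pairs)
    if (sloan_same_set) {
      pairs <- rbind(pairs, data.frame(source = names(loaded), dest = names(loaded)))
    }
    report$sloan <- purrr::pmap_dfr(pairs, function(source, dest) {
      stage(paste0("sloan/", source, "->", dest), 4, {
        fit <- fit_sloan(loaded[[source]], loaded[[dest]])
        cls <- classify_species(fit)
        fr <- classification_fractions(cls)
        tibble::tibble(
          source = source, dest = dest, N_T = fit$N_T, m = fit$m,
          r_squared = fit$r_squared, n_species = fr$n_species,
          frac_below = fr$frac_below, frac_neutral = fr$frac_neutral,
          frac_above = fr$frac_above
        )
      })
    })
  }
  if ("pnt" %in% run) {
    report$pnt <- purrr::imap_dfr(loaded, function(cm, nm) {
      stage(paste0("pnt/", nm), 5, {
        hnm_rows <- report$hnm[report$hnm$treatment == nm, ]
        purrr::map_dfr(colnames(cm), function(sid) {
          sad <- extract_sad(cm, sid)
          p_obs <- if (nrow(hnm_rows) > 0 && sid %in% hnm_rows$sample) {
            hnm_rows$pseudo_p[hnm_rows$sample == sid]
          } else {
            suppressWarnings(hnm_neutrality_test(sad, n_sim = n_sim, alpha = alpha)$pseudo_p)
          }
          out <- purrr::map_dfr(c("IF", "PC"), function(mdl) {
            pw <- suppressWarnings(run_power_analysis(
              sad, model = mdl, effect = if (mdl == "PC") min(pnt_effect, 1) else pnt_effect,
              n_datasets = pnt_n_datasets, n_sim_per_test = pnt_n_sim,
              alpha = alpha
            ))
            tibble::tibble(
              treatment = nm, sample = sid, model = mdl, effect = pw$effect,
              p_observed = p_obs, ave_p = pw$ave_p, power = pw$power,
              non_neutral_detected = detect_non_neutral(p_obs, pw$ave_p),
              false_negative = classify_false_negative(p_obs, pw$ave_p, alpha)
            )
          })
          out
        })
      })
    })
  }

  class(report) <- "untbx_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tab in c("hnm", "nsr", "msn", "sloan", "pnt")) {
      if (!is.null(report[[tab]]) && NROW(report[[tab]]) > 0) {
        readr::write_tsv(report[[tab]], file.path(out_dir, paste0(tab, ".tsv")),
                         progress = FALSE)
      }
    }
    jsonlite::write_json(
      report[setdiff(names(report), "schema_version")],
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
    )
    return(invisible(report))
  }
  report
}

#' @export
print.untbx_report <- function(x, ...) {
  cat("<untbx_report>", length(x$treatments), "treatment(s):",
      paste(x$treatments, collapse = ", "), "\n")
  for (tab in c("hnm", "nsr", "msn", "sloan", "pnt")) {
    if (!is.null(x[[tab]])) {
      cat(sprintf("$%s: %d rows\n", tab, NROW(x[[tab]])))
    }
  }
  invisible(x)
}
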