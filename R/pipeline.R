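#' End-to-end analysis pipeline
#'
#' Orchestrates phantom generation -> wall thickening and global function ->
#' velocity-encoded strain -> perfusion classification and salvage ->
#' paired statistics and ROC thresholds, writing CSV/JSON outputs and a run
#' log into an output directory. Deterministic given the configured seed.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; stage seeds are derived from it and recorded.
#' @param dysfunction radial-contraction multiplier inside the perfusion
#'   defect for the post-ischemia phantom (1 = no dysfunction).
#' @param n_chords chords per slice for the centerline method.
#' @param roc_steps thresholds per ROC scan.
#' @param n_subjects subjects in the simulated cohort used for the ROC stage.
#' @param wt_sd,strain_sd cohort standard deviations (mm / unitless).
#' @param hr_bpm named vector `c(pre=, post=)` of heart rates used for
#'   cardiac output.
#' @param substeps Runge-Kutta substeps per frame for tracking.
#' @param write_inputs also write the phantom input files (contour JSON,
#'   velocity NIfTI, polar CSV).
#' @param write_plots write bullseye/ROC PNG figures.
#' @param verbose log to stderr as well as to the run log.
#' @param ... overrides passed to [lv_phantom_spec()] (geometry, defect, ...).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("lvrun"), seed = 1L,
                            dysfunction = 0.25, n_chords = 80,
                            roc_steps = 1000, n_subjects = 10,
                            wt_sd = 0.5, strain_sd = 0.05,
                            hr_bpm = c(pre = 81, post = 113),
                            substeps = 2,
                            write_inputs = TRUE, write_plots = FALSE,
                            verbose = TRUE, ...) {
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), dysfunction = dysfunction,
      n_chords = n_chords, roc_steps = roc_steps, n_subjects = n_subjects,
      wt_sd = wt_sd, strain_sd = strain_sd, hr_bpm = hr_bpm,
      substeps = substeps, write_inputs = write_inputs,
      write_plots = write_plots, verbose = verbose,
      phantom_args = list(...)
    ),
    class = "pipeline_config"
  )
}

.run_stage <- function(stage, log, expr) {
  log(sprintf("stage %s: start", stage))
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

# per-class means of a named column over a 17-segment table with labels
.class_means <- function(values, labels) {
  vapply(
    c("ischemic", "adjacent", "remote"),
    function(cl) {
      if (any(labels == cl)) mean(values[labels == cl]) else NA_real_
    },
    numeric(1)
  )
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return the run summary (also written to `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) {
    writeLines(msg, log_con)
    if (config$verbose) message(msg)
  }
  log(sprintf("run_pipeline: seed %d, out %s", config$seed, config$out_dir))

  # ---- phantom -------------------------------------------------------------
  phantoms <- .run_stage("phantom", log, {
    mk <- function(dys, seed_offset) {
      args <- c(
        list(dysfunction_model = dys, seed = config$seed + seed_offset),
        config$phantom_args
      )
      make_lv_phantom(do.call(lv_phantom_spec, args))
    }
    list(pre = mk(1, 0L), post = mk(config$dysfunction, 1L))
  })
  if (config$write_inputs) {
    .run_stage("phantom-io", log, {
      for (ph in names(phantoms)) {
        p <- phantoms[[ph]]
        write_contours_json(
          p$sax, p$times,
          file.path(config$out_dir, sprintf("contours_%s.json", ph))
        )
        for (pl in names(p$velocity)) {
          write_velocity_nifti(
            p$velocity[[pl]],
            file.path(config$out_dir, sprintf("velocity_%s_%s", ph, pl))
          )
        }
      }
      write_polar_csv(
        phantoms$post$perfusion,
        file.path(config$out_dir, "perfusion_counts.csv")
      )
      write_polar_csv(
        phantoms$post$lge,
        file.path(config$out_dir, "lge_transmurality.csv")
      )
      utils::write.csv(
        phantoms$post$truth,
        file.path(config$out_dir, "ground_truth.csv"),
        row.names = FALSE
      )
      log("phantom-io: inputs written")
    })
  }

  # ---- wall thickening and global function ---------------------------------
  fun <- .run_stage("function", log, {
    out <- list()
    for (ph in names(phantoms)) {
      sax <- phantoms[[ph]]$sax
      th <- phantoms[[ph]]$spec$slice_thickness_mm
      gf <- compute_volumes_mass(sax, th, hr_bpm = config$hr_bpm[[ph]])
      wt <- stack_wall_thickening(sax, n_chords = config$n_chords)
      log(sprintf(
        "function [%s]: EDV %.1f ml, ESV %.1f ml, EF %.1f%%, mass %.1f ml",
        ph, gf$edv_ml, gf$esv_ml, gf$ef_percent, gf$lv_mass_ml
      ))
      out[[ph]] <- list(gf = gf, wt = wt)
    }
    out
  })
  gf_df <- do.call(rbind, lapply(names(fun), function(ph) {
    g <- fun[[ph]]$gf
    data.frame(
      phase = ph, edv_ml = g$edv_ml, esv_ml = g$esv_ml, sv_ml = g$sv_ml,
      ef_percent = g$ef_percent, hr_bpm = g$hr_bpm, co_l_min = g$co_l_min,
      lv_mass_ml = g$lv_mass_ml
    )
  }))
  utils::write.csv(gf_df, file.path(config$out_dir, "global_function.csv"),
    row.names = FALSE
  )

  # ---- velocity-encoded strain ----------------------------------------------
  strain <- .run_stage("strain", log, {
    out <- list()
    for (ph in names(phantoms)) {
      p <- phantoms[[ph]]
      es <- detect_es_frame(p$sax)
      fields <- lapply(names(p$velocity), function(pl) {
        pts <- p$lax[[pl]]$ed_points
        traj <- track_points(
          cbind(pts$x_mm, pts$z_mm), p$velocity[[pl]],
          substeps = config$substeps
        )
        compute_strain(traj, wall_elements(pts), es_frame = es)
      })
      out[[ph]] <- do.call(segment_strain, fields)
      log(sprintf(
        "strain [%s]: mean ES radial %.3f, longitudinal %.3f (ES frame %d)",
        ph, mean(out[[ph]]$radial_strain),
        mean(out[[ph]]$longitudinal_strain), es
      ))
    }
    out
  })

  # ---- perfusion classification and salvage ---------------------------------
  classify <- .run_stage("classify", log, {
    defect <- quantify_defect(phantoms$post$perfusion)
    fractions <- segment_ischemia_fractions(defect$mask)
    cls <- classify_segments(fractions)
    infarct <- infarct_size_from_transmurality(phantoms$post$lge)
    salvage <- compute_msi(infarct, defect$extent_pct)
    log(sprintf(
      "classify: AAR %.1f%% of LV, infarct %.1f%%, MSI %s; %d/%d/%d segments",
      defect$extent_pct, infarct,
      ifelse(salvage$undefined, "undefined", sprintf("%.2f", salvage$msi)),
      sum(cls$label == "ischemic"), sum(cls$label == "adjacent"),
      sum(cls$label == "remote")
    ))
    list(defect = defect, cls = cls, salvage = salvage)
  })
  utils::write.csv(classify$cls,
    file.path(config$out_dir, "classification.csv"),
    row.names = FALSE
  )

  # ---- per-segment table -----------------------------------------------------
  labels <- as.character(classify$cls$label)
  segments <- do.call(rbind, lapply(names(phantoms), function(ph) {
    wt <- fun[[ph]]$wt$per_segment
    st <- strain[[ph]]
    df <- merge(
      data.frame(
        segment = 1:17, phase = ph, class = labels,
        ischemia_fraction = classify$cls$ischemia_fraction
      ),
      merge(wt[c("segment", "ed_thickness_mm", "es_thickness_mm", "wt_mm", "fwt")],
        st[c("segment", "radial_strain", "longitudinal_strain")],
        by = "segment", all = TRUE
      ),
      by = "segment", all.x = TRUE
    )
    df
  }))
  utils::write.csv(segments, file.path(config$out_dir, "segments.csv"),
    row.names = FALSE
  )

  # ---- statistics and ROC ----------------------------------------------------
  stats_out <- .run_stage("stats", log, {
    by_class <- do.call(rbind, lapply(
      c("ischemic", "adjacent", "remote"),
      function(cl) {
        idx <- labels == cl
        pre <- segments[segments$phase == "pre", ]
        post <- segments[segments$phase == "post", ]
        p_wt <- if (sum(idx) >= 2) {
          paired_tests(pre$wt_mm[idx], post$wt_mm[idx], "t")$p_value
        } else {
          NA_real_
        }
        data.frame(
          class = cl, n_segments = sum(idx),
          wt_pre_mm = mean(pre$wt_mm[idx]), wt_post_mm = mean(post$wt_mm[idx]),
          wt_p = p_wt,
          radial_pre = mean(pre$radial_strain[idx]),
          radial_post = mean(post$radial_strain[idx]),
          longitudinal_pre = mean(pre$longitudinal_strain[idx]),
          longitudinal_post = mean(post$longitudinal_strain[idx])
        )
      }
    ))

    counts <- table(factor(labels, c("ischemic", "adjacent", "remote")))
    thresholds <- NULL
    roc_skipped <- NULL
    rocs <- NULL
    if (any(counts == 0)) {
      roc_skipped <- sprintf(
        "class error: empty class(es) %s; ROC stage skipped",
        paste(names(counts)[counts == 0], collapse = ", ")
      )
      log(paste("stats:", roc_skipped))
    } else {
      # simulated cohort around the measured per-class phantom means
      mk_means <- function(pre_col, post_col) {
        pre <- segments[segments$phase == "pre", ]
        post <- segments[segments$phase == "post", ]
        m_pre <- .class_means(pre[[pre_col]], labels)
        m_post <- .class_means(post[[post_col]], labels)
        lapply(
          stats::setNames(nm = c("ischemic", "adjacent", "remote")),
          function(cl) c(pre = m_pre[[cl]], post = m_post[[cl]])
        )
      }
      params <- segment_sim_params(
        wt_mean = mk_means("wt_mm", "wt_mm"),
        radial_mean = mk_means("radial_strain", "radial_strain"),
        longitudinal_mean = mk_means(
          "longitudinal_strain", "longitudinal_strain"
        ),
        wt_sd = config$wt_sd, radial_sd = config$strain_sd,
        longitudinal_sd = config$strain_sd,
        n_subjects = config$n_subjects,
        segments_per_class = stats::setNames(
          as.integer(counts), names(counts)
        ),
        seed = config$seed + 2L
      )
      cohort <- sample_segment_dataset(params, labels = labels)
      rt <- roc_table(
        cohort[cohort$phase == "post", ],
        n_steps = config$roc_steps
      )
      thresholds <- rt$table
      rocs <- rt$roc
      utils::write.csv(thresholds,
        file.path(config$out_dir, "thresholds.csv"),
        row.names = FALSE
      )
      curves <- do.call(rbind, lapply(rocs, function(r) {
        data.frame(
          comparison = r$comparison, threshold = r$thresholds,
          sensitivity = r$sensitivity, specificity = r$specificity
        )
      }))
      utils::write.csv(curves, file.path(config$out_dir, "roc_curves.csv"),
        row.names = FALSE
      )
      log(sprintf(
        "stats: %d threshold rows over %d cohort segments",
        nrow(thresholds), sum(cohort$phase == "post")
      ))
    }
    list(
      by_class = by_class, thresholds = thresholds,
      roc_skipped = roc_skipped, rocs = rocs
    )
  })
  utils::write.csv(stats_out$by_class,
    file.path(config$out_dir, "class_summary.csv"),
    row.names = FALSE
  )

  if (config$write_plots) {
    .run_stage("figures", log, {
      pb <- function(vals, name, title) {
        grDevices::png(file.path(config$out_dir, name), 600, 600)
        print(plot_bullseye(vals, title))
        grDevices::dev.off()
      }
      pb(
        reduce_polar(phantoms$post$perfusion),
        "bullseye_perfusion.png", "perfusion counts"
      )
      pb(
        as.numeric(factor(labels, c("remote", "adjacent", "ischemic"))),
        "bullseye_classification.png", "classification"
      )
      wt_post <- segments[segments$phase == "post", ]
      pb(wt_post$wt_mm, "bullseye_wt_post.png", "wall thickening (post)")
      if (!is.null(stats_out$rocs)) {
        for (nm in names(stats_out$rocs)) {
          grDevices::png(
            file.path(config$out_dir, paste0("roc_", nm, ".png")), 600, 600
          )
          print(plot_roc(stats_out$rocs[[nm]]))
          grDevices::dev.off()
        }
      }
      log("figures written")
    })
  }

  summary <- list(
    seed = config$seed,
    global_function = gf_df,
    class_summary = stats_out$by_class,
    segments = segments,
    classification = classify$cls,
    salvage = classify$salvage[c("aar_pct", "infarct_pct", "msi", "undefined")],
    thresholds = if (is.null(stats_out$thresholds)) {
      NULL
    } else {
      stats_out$thresholds[stats_out$thresholds$comparison != "adjacent", ]
    },
    thresholds_full = stats_out$thresholds,
    roc_skipped = stats_out$roc_skipped
  )
  jsonlite::write_json(
    summary, file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
  )
  log("run_pipeline: done")
  invisible(summary)
}
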