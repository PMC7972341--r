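# Figure builders for the pair report. Every number drawn here comes from
# the mp_pair_report object; no statistic is computed at plot time.

# fixed R1-R4 palette, consistent across all plots of one report
quadrant_palette <- function(palette = NULL) {
  palette %||% c(R1 = "#E64B35", R2 = "#4DBBD5", R3 = "#00A087",
                 R4 = "#3C5488")
}

fmt_p <- function(p) {
  if (is.null(p) || is.na(p)) "p = NA" else paste0("p = ", signif(p, 2))
}

plot_response_boxplot <- function(box, marker_name) {
  ggplot2::ggplot(box$data, ggplot2::aes(x = .data$response, y = .data$value,
                                         fill = .data$response)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(neg = "#8491B4", pos = "#DC0000")) +
    ggplot2::labs(title = marker_name, subtitle = paste("Wilcoxon",
                                                        fmt_p(box$wilcoxon$p_value)),
                  x = "response", y = marker_name) +
    ggplot2::theme_bw() + ggplot2::theme(legend.position = "none")
}

plot_response_scatter <- function(scatter, m1_name, m2_name, cutpoints) {
  g <- ggplot2::ggplot(scatter$data,
                       ggplot2::aes(x = .data$m1, y = .data$m2,
                                    color = .data$response)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(neg = "#8491B4", pos = "#DC0000")) +
    ggplot2::labs(title = paste(m1_name, "vs", m2_name),
                  subtitle = paste0("Spearman R = ",
                                    signif(scatter$spearman$estimate, 2),
                                    ", ", fmt_p(scatter$spearman$p_value)),
                  x = m1_name, y = m2_name) +
    ggplot2::theme_bw()
  if (!is.na(cutpoints["m1"])) {
    g <- g + ggplot2::geom_vline(xintercept = cutpoints[["m1"]],
                                 linetype = "dashed")
  }
  if (!is.na(cutpoints["m2"])) {
    g <- g + ggplot2::geom_hline(yintercept = cutpoints[["m2"]],
                                 linetype = "dashed")
  }
  g
}

plot_response_roc <- function(roc) {
  auc_lab <- vapply(names(roc$auc), function(nm) {
    a <- roc$auc[[nm]]
    if (is.null(a)) return(NA_character_)
    sprintf("AUC %.3f (%.3f-%.3f)", a$auc, a$ci_low, a$ci_high)
  }, character(1))
  ggplot2::ggplot(roc$curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                           color = .data$model)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(title = "ROC of the four logistic models",
                  subtitle = paste(stats::na.omit(auc_lab), collapse = "; "),
                  x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_bw()
}

quadrant_grid <- function(quadrants) {
  pos <- tibble::tibble(
    quadrant = c("R1", "R2", "R3", "R4"),
    x = c(2, 1, 1, 2), y = c(2, 2, 1, 1)
  )
  dplyr::left_join(quadrants, pos, by = "quadrant")
}

plot_quadrant_area <- function(quadrants, independence, title, palette) {
  qd <- quadrant_grid(quadrants)
  total <- sum(qd$n)
  qd$side <- sqrt(qd$n / max(1, total))
  ggplot2::ggplot(qd) +
    ggplot2::geom_tile(ggplot2::aes(x = .data$x, y = .data$y,
                                    width = .data$side,
                                    height = .data$side,
                                    fill = .data$quadrant)) +
    ggplot2::geom_text(ggplot2::aes(x = .data$x, y = .data$y,
                                    label = paste0(.data$quadrant,
                                                   "\nn=", .data$n))) +
    ggplot2::scale_fill_manual(values = palette) +
    ggplot2::labs(title = title,
                  subtitle = paste("Fisher independence",
                                   fmt_p(independence$p_value))) +
    ggplot2::theme_void() + ggplot2::theme(legend.position = "none")
}

plot_response_matrix <- function(quadrants, palette) {
  qd <- quadrant_grid(quadrants)
  qd$label <- ifelse(is.na(qd$rate), paste0(qd$quadrant, "\nn=0"),
                     sprintf("%s\nn=%d\n%.0f%% (%.2f-%.2f)", qd$quadrant,
                             qd$n, 100 * qd$rate, qd$ci_low, qd$ci_high))
  ggplot2::ggplot(qd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$quadrant), alpha = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_manual(values = palette) +
    ggplot2::labs(title = "Response rate by quadrant (95% CI)") +
    ggplot2::theme_void() + ggplot2::theme(legend.position = "none")
}

plot_response_doughnut <- function(quadrants, palette) {
  qd <- quadrants[quadrants$n > 0, , drop = FALSE]
  total <- sum(qd$n)
  # ring width encodes relative group size; colored arc = response rate
  qd$r0 <- cumsum(c(0, utils::head(qd$n, -1))) / total + 0.2
  qd$r1 <- cumsum(qd$n) / total + 0.2
  arc <- dplyr::bind_rows(
    tibble::tibble(quadrant = qd$quadrant, r0 = qd$r0, r1 = qd$r1,
                   a0 = 0, a1 = qd$rate, part = "responder"),
    tibble::tibble(quadrant = qd$quadrant, r0 = qd$r0, r1 = qd$r1,
                   a0 = qd$rate, a1 = 1, part = "non-responder")
  )
  ggplot2::ggplot(arc) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$r0, xmax = .data$r1,
                                    ymin = .data$a0, ymax = .data$a1,
                                    fill = .data$quadrant,
                                    alpha = .data$part),
                       color = "white") +
    ggplot2::scale_fill_manual(values = palette) +
    ggplot2::scale_alpha_manual(values = c(responder = 1,
                                           `non-responder` = 0.25)) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(title = "Group size (ring width) and response rate (arc)") +
    ggplot2::theme_void()
}

plot_response_line <- function(quadrants, m1_name, m2_name,
                               interaction_p = NA_real_) {
  qd <- quadrant_grid(quadrants)
  qd$m1_level <- ifelse(qd$x == 2, "high", "low")
  qd$m2_level <- ifelse(qd$y == 2, "high", "low")
  ggplot2::ggplot(qd, ggplot2::aes(x = .data$m1_level, y = .data$rate,
                                   group = .data$m2_level,
                                   color = .data$m2_level)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.1) +
    ggplot2::labs(title = "Response rate by quadrant",
                  subtitle = paste("interaction Wald", fmt_p(interaction_p)),
                  x = paste(m1_name, "level"), y = "response rate",
                  color = paste(m2_name, "level")) +
    ggplot2::theme_bw()
}

km_curve_df <- function(curves) {
  dplyr::bind_rows(lapply(names(curves), function(nm) {
    km <- curves[[nm]]
    cv <- km$curve
    # prepend t=0, S=1 so the step starts at the origin
    dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1, group = nm),
      tibble::tibble(time = cv$time, survival = cv$survival, group = nm)
    )
  }))
}

plot_km_group <- function(kg, title, colors = NULL) {
  df <- km_curve_df(kg$curves)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                        color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = title,
                  subtitle = paste("log-rank",
                                   fmt_p(kg$logrank$p_value %||% NA_real_)),
                  x = "time", y = "survival") +
    ggplot2::theme_bw()
  if (!is.null(colors)) g <- g + ggplot2::scale_color_manual(values = colors)
  g
}

plot_km_quadrants <- function(km_quadrants, logrank, palette) {
  kg <- list(curves = km_quadrants, logrank = logrank)
  plot_km_group(kg, "Survival by quadrant", colors = palette)
}

plot_surv_matrix <- function(quadrants, palette) {
  qd <- quadrant_grid(quadrants)
  qd$label <- sprintf("%s\nn=%d\nmedian %s (%s-%s)", qd$quadrant, qd$n,
                      signif(qd$median, 3), signif(qd$median_ci_low, 3),
                      signif(qd$median_ci_high, 3))
  ggplot2::ggplot(qd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$quadrant), alpha = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_manual(values = palette) +
    ggplot2::labs(title = "Median survival by quadrant (95% CI)") +
    ggplot2::theme_void() + ggplot2::theme(legend.position = "none")
}

plot_surv_line <- function(quadrants, m1_name, m2_name,
                           interaction_p = NA_real_) {
  qd <- quadrant_grid(quadrants)
  qd$m1_level <- ifelse(qd$x == 2, "high", "low")
  qd$m2_level <- ifelse(qd$y == 2, "high", "low")
  ggplot2::ggplot(qd, ggplot2::aes(x = .data$m1_level, y = .data$median,
                                   group = .data$m2_level,
                                   color = .data$m2_level)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(title = "Median survival by quadrant",
                  subtitle = paste("interaction Wald", fmt_p(interaction_p)),
                  x = paste(m1_name, "level"), y = "median survival",
                  color = paste(m2_name, "level")) +
    ggplot2::theme_bw()
}

plot_km_conditional <- function(cond, m1_name, m2_name) {
  blocks <- list(
    c("m1_is", "high"), c("m1_is", "low"), c("m2_is", "high"),
    c("m2_is", "low")
  )
  df <- dplyr::bind_rows(lapply(blocks, function(b) {
    kg <- cond[[b[1]]][[b[2]]]
    if (length(kg$curves) == 0L) return(NULL)
    strat_marker <- if (b[1] == "m1_is") m1_name else m2_name
    test_marker <- if (b[1] == "m1_is") m2_name else m1_name
    d <- km_curve_df(kg$curves)
    d$panel <- paste0(test_marker, " | ", strat_marker, " ", b[2],
                      " (", fmt_p(kg$logrank$p_value %||% NA_real_), ")")
    d
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = "Conditional Kaplan-Meier curves",
                  x = "time", y = "survival") +
    ggplot2::theme_bw()
}

#' Build all figures of a pair report
#'
#' Turns an [build_pair_report()] object into a named list of ggplot
#' objects: eight response-side figures (two boxplots, scatter, ROC,
#' area-proportion chart, quadrant matrix, doughnut, interaction line chart)
#' and seven survival-side figures (two single-marker KM plots, quadrant KM,
#' survival area-proportion chart, survival matrix, median-survival line
#' chart, conditional KM panel). Sections absent from the report produce no
#' figures.
#'
#' @param report An `mp_pair_report`.
#' @param palette Named R1-R4 color vector; default fixed palette.
#' @return Named list of ggplot objects.
#' @export
pair_report_plots <- function(report, palette = NULL) {
  pal <- quadrant_palette(palette)
  plots <- list()
  rs <- report$response_section
  if (!is.null(rs)) {
    ip <- if (rs$four_model$status == "evaluated") {
      rs$four_model$interaction_wald_p
    } else {
      NA_real_
    }
    plots$response_boxplot_m1 <- plot_response_boxplot(rs$boxplots$m1,
                                                       report$m1$name)
    plots$response_boxplot_m2 <- plot_response_boxplot(rs$boxplots$m2,
                                                       report$m2$name)
    plots$response_scatter <- plot_response_scatter(rs$scatter,
                                                    report$m1$name,
                                                    report$m2$name,
                                                    report$cutpoints)
    if (!is.null(rs$roc)) plots$response_roc <- plot_response_roc(rs$roc)
    plots$response_area_prop <- plot_quadrant_area(
      rs$quadrants$quadrants, rs$quadrants$independence,
      "Quadrant sizes (response)", pal)
    plots$response_quadrant_matrix <- plot_response_matrix(
      rs$quadrants$quadrants, pal)
    plots$response_doughnut <- plot_response_doughnut(
      rs$quadrants$quadrants, pal)
    plots$response_line <- plot_response_line(rs$quadrants$quadrants,
                                              report$m1$name,
                                              report$m2$name, ip)
  }
  ss <- report$survival_section
  if (!is.null(ss)) {
    ip <- if (ss$four_model$status == "evaluated") {
      ss$four_model$interaction_wald_p
    } else {
      NA_real_
    }
    plots$surv_km_m1 <- plot_km_group(ss$km_m1,
                                      paste("Survival by", report$m1$name))
    plots$surv_km_m2 <- plot_km_group(ss$km_m2,
                                      paste("Survival by", report$m2$name))
    plots$surv_km_quadrants <- plot_km_quadrants(
      ss$km_quadrants, ss$quadrant_stats$logrank, pal)
    plots$surv_area_prop <- plot_quadrant_area(
      ss$quadrant_stats$quadrants, ss$quadrant_stats$independence,
      "Quadrant sizes (survival)", pal)
    plots$surv_matrix <- plot_surv_matrix(ss$quadrant_stats$quadrants, pal)
    plots$surv_line <- plot_surv_line(ss$quadrant_stats$quadrants,
                                      report$m1$name, report$m2$name, ip)
    plots$surv_km_conditional <- plot_km_conditional(ss$conditional_curves,
                                                     report$m1$name,
                                                     report$m2$name)
  }
  plots
}

#' Render a pair report to figure files and a statistics JSON
#'
#' Writes one figure file per plot (deterministic names) and the complete
#' statistics of the report as JSON. Rendering is side-effect-only: nothing
#' is computed here that is not already in the report object.
#'
#' @param report An `mp_pair_report`.
#' @param out_dir Output directory (created if needed).
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param figures Set `FALSE` to write the statistics JSON only.
#' @param palette Optional named R1-R4 color vector.
#' @return A tibble manifest (`name`, `file`, `kind`), invisibly the side
#'   effect of the written files.
#' @export
render_pair_report <- function(report, out_dir, format = c("png", "svg", "pdf"),
                               figures = TRUE, palette = NULL) {
  format <- match.arg(format)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    mp_stop(paste0("cannot create output directory: ", out_dir))
  }
  manifest <- list()
  if (figures) {
    plots <- pair_report_plots(report, palette = palette)
    for (nm in names(plots)) {
      file <- file.path(out_dir, paste0(nm, ".", format))
      ggplot2::ggsave(file, plots[[nm]], width = 6, height = 5, dpi = 150)
      manifest[[length(manifest) + 1L]] <-
        tibble::tibble(name = nm, file = file, kind = "figure")
    }
  }
  stats_file <- file.path(out_dir, "pair_stats.json")
  jsonlite::write_json(pair_report_stats(report), stats_file,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  manifest[[length(manifest) + 1L]] <-
    tibble::tibble(name = "pair_stats", file = stats_file, kind = "stats")
  invisible(dplyr::bind_rows(manifest))
}
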