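# Diagnostic plots: the cohort ROH-vs-IR scatter and per-chromosome
# allele-fraction views. Functions return ggplot objects (pure functions of
# the saved tables); save_plot() writes them to disk.

#' Cohort scatter: ROH fraction vs inheritance ratio
#'
#' One point per (sample, chromosome). Duo/trio rows are drawn as ROH
#' fraction (x) against IR (y) with background shading at the configured
#' thresholds (the same values used for tagging, never a second copy);
#' single rows, which have no IR, are drawn as ROH fraction against
#' chromosome. Rows with a UPD candidate call are labeled.
#'
#' @param cohort [build_cohort_table()] output (or the TSV re-read).
#' @param thresholds `thresholds` section of the config used for tagging.
#' @param mode "auto" picks duo/trio vs single by setup content; or force
#'   "duo_trio" / "single".
#' @return ggplot object.
#' @export
plot_cohort_scatter <- function(cohort, thresholds = upd_config()$thresholds,
                                mode = c("auto", "duo_trio", "single")) {
  mode <- match.arg(mode)
  if (!nrow(cohort)) stopf("empty cohort table")
  tab <- data.table::as.data.table(cohort)
  if (mode == "auto")
    mode <- if (any(tab$setup != "single")) "duo_trio" else "single"
  lab <- tab[upd_call != "none"]
  if (mode == "duo_trio") {
    tab <- tab[setup != "single" & !is.na(ir)]
    if (!nrow(tab)) stopf("no duo/trio rows with informative IR to plot")
    lab <- tab[upd_call != "none"]
    ymax <- max(tab$ir, thresholds$ir_trio * 2, na.rm = TRUE)
    ylo <- 0.8 * min(tab$ir, 1, na.rm = TRUE)  # ir >= 1 by construction
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = roh_fraction, y = ir)) +
      ggplot2::annotate("rect", xmin = thresholds$roh_high_min, xmax = 1,
                        ymin = ylo, ymax = Inf, fill = "#E69F00",
                        alpha = 0.25) +
      ggplot2::annotate("rect", xmin = thresholds$roh_low_max,
                        xmax = thresholds$roh_high_min, ymin = ylo,
                        ymax = Inf, fill = "#F0E442", alpha = 0.25) +
      ggplot2::annotate("rect", xmin = 0, xmax = thresholds$roh_low_max,
                        ymin = thresholds$ir_trio, ymax = Inf,
                        fill = "#E69F00", alpha = 0.18) +
      ggplot2::geom_hline(yintercept = c(thresholds$ir_duo,
                                         thresholds$ir_trio),
                          linetype = "dashed", color = "grey40") +
      ggplot2::geom_point(ggplot2::aes(shape = setup), alpha = 0.6) +
      ggplot2::scale_y_continuous(trans = "log10",
                                  limits = c(ylo, ymax * 1.2)) +
      ggplot2::labs(x = "ROH fraction", y = "inheritance ratio (log scale)",
                    title = "Cohort screen: ROH fraction vs inheritance ratio")
  } else {
    tab <- tab[, chrom_i := chrom_order(chrom)]
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = roh_fraction, y = chrom_i)) +
      ggplot2::annotate("rect", xmin = thresholds$roh_high_min, xmax = 1,
                        ymin = -Inf, ymax = Inf, fill = "#E69F00",
                        alpha = 0.25) +
      ggplot2::annotate("rect", xmin = thresholds$roh_low_max,
                        xmax = thresholds$roh_high_min, ymin = -Inf,
                        ymax = Inf, fill = "#F0E442", alpha = 0.25) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::scale_y_continuous(breaks = 1:22) +
      ggplot2::labs(x = "ROH fraction", y = "chromosome",
                    title = "Cohort screen (single setups): ROH fraction")
  }
  if (nrow(lab))
    p <- p + ggplot2::geom_text(
      data = lab, ggplot2::aes(label = paste0(sample, ":chr", chrom)),
      vjust = -0.8, size = 2.7, color = "#B2182B")
  p + ggplot2::theme_bw()
}

#' Allele-fraction plot for one chromosome
#'
#' Main panel: alternate-allele fraction against position, colored by
#' parental origin, with called ROH segments drawn as a track above.
#' A right-hand strip shows the relative IR (maternal / (maternal +
#' paternal)) and the ROH fraction as bars. Under biparental inheritance the
#' colors balance and the relative IR sits near 0.5; maternal heterodisomy
#' empties the paternal color and pushes it to 1; isodisomy shifts real
#' variants to fraction 1 while recurrent artifacts stay in the 0.2 band.
#'
#' @param sites joined site table of one sample (will be subset to `chrom`).
#' @param metrics the matching [chromosome_metrics()] row.
#' @param segments ROH segment table (subset to `chrom` internally).
#' @param chrom chromosome to draw.
#' @param cfg [upd_config()] (origin colors).
#' @return ggplot object.
#' @export
plot_chromosome_af <- function(sites, metrics, segments, chrom,
                               cfg = upd_config()) {
  cc <- chrom
  sub <- data.table::as.data.table(sites)[chrom == cc]
  if (!nrow(sub)) {
    warnf("no sites on chr%s; empty plot", cc)
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = paste0("chr", cc, ": no sites")))
  }
  if (!"origin" %in% names(sub))
    sub[, origin := classify_origin(gt, mother_status, father_status)]
  m <- data.table::as.data.table(metrics)[chrom == cc]
  segs <- data.table::as.data.table(segments)
  segs <- if (nrow(segs)) segs[chrom == cc] else segs
  xmax <- max(sub$pos)
  bar_x0 <- xmax * 1.05
  bar_w <- xmax * 0.04
  rel <- m$relative_ir
  rohf <- m$roh_fraction
  p <- ggplot2::ggplot(sub, ggplot2::aes(x = pos, y = alt_fraction)) +
    ggplot2::geom_point(ggplot2::aes(color = origin), size = 0.8,
                        alpha = 0.8) +
    ggplot2::scale_color_manual(values = cfg$plot$origin_colors) +
    ggplot2::coord_cartesian(ylim = c(0, 1.12), clip = "off") +
    ggplot2::labs(x = paste0("position on chr", cc),
                  y = "alternate-allele fraction",
                  subtitle = sprintf(
                    "relative IR = %s; ROH fraction = %.3f",
                    ifelse(is.na(rel), "NA", sprintf("%.3f", rel)), rohf)) +
    ggplot2::theme_bw()
  if (nrow(segs))
    p <- p + ggplot2::annotate("segment", x = segs$start, xend = segs$end,
                               y = 1.08, yend = 1.08, linewidth = 2.5,
                               color = "#B2182B")
  # side bars: relative IR and ROH fraction
  bars <- data.table::data.table(
    x = c(bar_x0, bar_x0 + 1.6 * bar_w),
    h = c(ifelse(is.na(rel), 0, rel), rohf),
    lab = c("rel. IR", "ROH"))
  p + ggplot2::annotate("rect", xmin = bars$x, xmax = bars$x + bar_w,
                        ymin = 0, ymax = bars$h,
                        fill = c("#D55E00", "#B2182B"), alpha = 0.8) +
    ggplot2::annotate("text", x = bars$x + bar_w / 2, y = -0.05,
                      label = bars$lab, size = 2.5)
}

#' Save a plot to PNG or SVG
#'
#' @param p ggplot object.
#' @param path output file; format from the extension.
#' @param cfg [upd_config()] (size/dpi).
#' @export
save_plot <- function(p, path, cfg = upd_config()) {
  ggplot2::ggsave(path, p, width = cfg$plot$width, height = cfg$plot$height,
                  dpi = cfg$plot$dpi)
  invisible(path)
}
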