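#' Polar layout of one iris-plot panel
#'
#' Bars (one per ranked condition) are arranged on a circle: disease groups
#' occupy contiguous sectors ordered clockwise by their clock-face position
#' (12 o'clock = 0 degrees, clockwise positive; groups sharing an hour
#' follow the figure-legend order), each sector's angular width is
#' proportional to its number of bars, and bars within a sector are ordered
#' by descending frequency ratio. Bar length encodes the frequency ratio on
#' the panel's own radial scale.
#'
#' @param results Ranked conditions of one stratum: data frame with
#'   `code`, `freq_ratio` and `disease_group` columns.
#' @param scheme A [disease_groups()] scheme.
#' @return List with `sectors` (group, start/end angle in degrees, bar
#'   count) and `bars` (code, group, ratio, start/end angle) — angles
#'   strictly clockwise-increasing, every bar inside its group's sector.
#' @export
iris_layout <- function(results, scheme = disease_groups()) {
  if (!nrow(results)) stopf("cannot lay out an empty result list")
  if (!all(c("code", "freq_ratio", "disease_group") %in% names(results)))
    stopf("results must carry code, freq_ratio and disease_group")
  ord_groups <- scheme$groups[order(scheme$groups$clock_hour), ]
  present <- ord_groups[ord_groups$group %in% results$disease_group, ]
  n_total <- nrow(results)
  counts <- vapply(present$group,
                   function(g) sum(results$disease_group == g), integer(1))
  width <- 360 * counts / n_total
  end <- cumsum(width)
  start <- c(0, end[-length(end)])
  sectors <- data.frame(group = present$group, label = present$label,
                        start = start, end = end, n = counts,
                        stringsAsFactors = FALSE)
  bars <- do.call(rbind, lapply(seq_len(nrow(sectors)), function(i) {
    r <- results[results$disease_group == sectors$group[i], , drop = FALSE]
    r <- r[order(-r$freq_ratio, r$code), , drop = FALSE]
    k <- nrow(r)
    w <- (sectors$end[i] - sectors$start[i]) / k
    data.frame(code = r$code, group = sectors$group[i],
               freq_ratio = r$freq_ratio,
               start = sectors$start[i] + (seq_len(k) - 1) * w,
               end = sectors$start[i] + seq_len(k) * w,
               stringsAsFactors = FALSE)
  }))
  rownames(bars) <- NULL
  list(sectors = sectors, bars = bars)
}

iris_palette <- function(scheme) {
  cols <- grDevices::hcl.colors(nrow(scheme$groups), "Dark 3")
  names(cols) <- scheme$groups$group
  cols
}

# clockwise-from-12 polar to cartesian (y grows downward on the canvas)
polar_xy <- function(cx, cy, r, theta_deg) {
  th <- theta_deg * pi / 180
  list(x = cx + r * sin(th), y = cy - r * cos(th))
}

panel_title <- function(setting, period) {
  sprintf("%s care, %s-index window",
          if (setting == "secondary") "Secondary" else "Primary", period)
}

# geometry shared by the SVG writer and the PNG renderer
iris_geometry <- function(ranked, scheme) {
  keys <- data.frame(
    setting = c("secondary", "secondary", "primary", "primary"),
    period = c("pre", "post", "pre", "post"),
    cx = c(300, 820, 300, 820), cy = c(260, 260, 710, 710),
    stringsAsFactors = FALSE)
  r0 <- 30; rmax <- 185
  panels <- lapply(seq_len(nrow(keys)), function(i) {
    r <- ranked[ranked$setting == keys$setting[i] &
                  ranked$period == keys$period[i], , drop = FALSE]
    if (!nrow(r)) return(NULL)
    lay <- iris_layout(r, scheme)
    max_ratio <- max(lay$bars$freq_ratio)
    lay$bars$r0 <- r0
    lay$bars$r1 <- r0 + (lay$bars$freq_ratio / max_ratio) * (rmax - r0)
    list(setting = keys$setting[i], period = keys$period[i],
         cx = keys$cx[i], cy = keys$cy[i], r0 = r0, rmax = rmax,
         max_ratio = max_ratio, layout = lay,
         title = panel_title(keys$setting[i], keys$period[i]))
  })
  list(panels = panels[!vapply(panels, is.null, logical(1))],
       width = 1200, height = 950, palette = iris_palette(scheme),
       scheme = scheme)
}

wedge_points <- function(cx, cy, r0, r1, a0, a1) {
  p1 <- polar_xy(cx, cy, r0, a0); p2 <- polar_xy(cx, cy, r1, a0)
  p3 <- polar_xy(cx, cy, r1, a1); p4 <- polar_xy(cx, cy, r0, a1)
  list(x = c(p1$x, p2$x, p3$x, p4$x), y = c(p1$y, p2$y, p3$y, p4$y))
}

svg_num <- function(x) sprintf("%.2f", x)

iris_svg_lines <- function(geom) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            geom$width, geom$height, geom$width, geom$height),
    '<rect width="100%" height="100%" fill="white"/>',
    sprintf('<text x="%s" y="30" font-size="20" text-anchor="middle" font-family="sans-serif">Leading conditions by case/control frequency ratio</text>',
            svg_num(geom$width / 2))
  )
  for (p in geom$panels) {
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="15" text-anchor="middle" font-family="sans-serif">%s</text>',
      svg_num(p$cx), svg_num(p$cy - p$rmax - 22), esc(p$title)))
    for (rr in c(0.5, 1)) {
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#cccccc" stroke-dasharray="4 3"/>',
        svg_num(p$cx), svg_num(p$cy),
        svg_num(p$r0 + rr * (p$rmax - p$r0))))
    }
    # per-panel radial scale annotation (panels use different scales)
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="12" text-anchor="middle" font-family="sans-serif" class="scale-label">ratio %s</text>',
      svg_num(p$cx), svg_num(p$cy + p$rmax + 18), svg_num(p$max_ratio)))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="middle" fill="#888888" font-family="sans-serif">ratio %s</text>',
      svg_num(p$cx), svg_num(p$cy - (p$r0 + 0.5 * (p$rmax - p$r0)) - 3),
      svg_num(p$max_ratio / 2)))
    b <- p$layout$bars
    gap <- pmin(0.15 * (b$end - b$start), 0.5)
    for (i in seq_len(nrow(b))) {
      w <- wedge_points(p$cx, p$cy, b$r0[i], b$r1[i],
                        b$start[i] + gap[i], b$end[i] - gap[i])
      out <- c(out, sprintf(
        '<path d="M %s %s L %s %s L %s %s L %s %s Z" fill="%s"><title>%s</title></path>',
        svg_num(w$x[1]), svg_num(w$y[1]), svg_num(w$x[2]), svg_num(w$y[2]),
        svg_num(w$x[3]), svg_num(w$y[3]), svg_num(w$x[4]), svg_num(w$y[4]),
        geom$palette[b$group[i]],
        esc(sprintf("%s (%.2f)", b$code[i], b$freq_ratio[i]))))
    }
  }
  g <- geom$scheme$groups
  pal <- geom$palette
  y0 <- 120
  out <- c(out, sprintf(
    '<text x="1060" y="%s" font-size="14" font-family="sans-serif">Disease groups</text>',
    svg_num(y0 - 20)))
  for (i in seq_len(nrow(g))) {
    out <- c(out, sprintf(
      '<rect x="1060" y="%s" width="12" height="12" fill="%s" class="legend-swatch"/>',
      svg_num(y0 + (i - 1) * 24), pal[g$group[i]]))
    out <- c(out, sprintf(
      '<text x="1078" y="%s" font-size="11" font-family="sans-serif" class="legend-label">%s</text>',
      svg_num(y0 + (i - 1) * 24 + 10), esc(g$label[i])))
  }
  c(out, "</svg>")
}

iris_png <- function(geom, path) {
  grDevices::png(path, width = geom$width, height = geom$height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, geom$width), ylim = c(geom$height, 0),
                        asp = 1)
  graphics::text(geom$width / 2, 30,
                 "Leading conditions by case/control frequency ratio",
                 cex = 1.4)
  for (p in geom$panels) {
    graphics::text(p$cx, p$cy - p$rmax - 22, p$title, cex = 1.1)
    graphics::symbols(rep(p$cx, 2), rep(p$cy, 2),
                      circles = p$r0 + c(0.5, 1) * (p$rmax - p$r0),
                      inches = FALSE, add = TRUE, fg = "#cccccc", lty = 3)
    graphics::text(p$cx, p$cy + p$rmax + 18,
                   sprintf("ratio %.2f", p$max_ratio), cex = 0.9)
    b <- p$layout$bars
    gap <- pmin(0.15 * (b$end - b$start), 0.5)
    for (i in seq_len(nrow(b))) {
      w <- wedge_points(p$cx, p$cy, b$r0[i], b$r1[i],
                        b$start[i] + gap[i], b$end[i] - gap[i])
      graphics::polygon(w$x, w$y, col = geom$palette[b$group[i]],
                        border = NA)
    }
  }
  g <- geom$scheme$groups
  y0 <- 120
  graphics::text(1060, y0 - 20, "Disease groups", adj = 0, cex = 1)
  for (i in seq_len(nrow(g))) {
    graphics::rect(1060, y0 + (i - 1) * 24, 1072, y0 + (i - 1) * 24 + 12,
                   col = geom$palette[g$group[i]], border = NA)
    graphics::text(1078, y0 + (i - 1) * 24 + 8, g$label[i], adj = 0,
                   cex = 0.8)
  }
  invisible(path)
}

#' Render the four-panel iris plot
#'
#' One figure with four polar panels (secondary/primary care x pre/post
#' window). Bar length encodes the frequency ratio on each panel's own
#' radial scale; colour encodes the disease group, with all fourteen groups
#' in the legend. The SVG output is plain text and byte-identical across
#' runs for identical inputs.
#'
#' @param ranked Ranked result table covering one or more strata, with
#'   `setting`, `period`, `code`, `freq_ratio`, `disease_group` columns.
#' @param file_prefix Output path without extension; `<prefix>.svg` and
#'   `<prefix>.png` are written.
#' @param scheme A [disease_groups()] scheme.
#' @param formats Subset of `c("svg", "png")`.
#' @return Character vector of the files written, invisibly.
#' @export
render_iris <- function(ranked, file_prefix, scheme = disease_groups(),
                        formats = c("svg", "png")) {
  if (!nrow(ranked)) stopf("cannot render an empty result table")
  geom <- iris_geometry(ranked, scheme)
  if (!length(geom$panels)) stopf("no stratum in the result table")
  written <- character(0)
  if ("svg" %in% formats) {
    path <- paste0(file_prefix, ".svg")
    con <- file(path, open = "wb")
    writeLines(iris_svg_lines(geom), con, sep = "\n")
    close(con)
    written <- c(written, path)
  }
  if ("png" %in% formats) {
    path <- paste0(file_prefix, ".png")
    iris_png(geom, path)
    written <- c(written, path)
  }
  invisible(written)
}
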