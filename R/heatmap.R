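#' Heatmap style: the six equity colors
#'
#' One color per equity level — red Absent, orange Highly Inadequate, light
#' orange Inadequate, teal Adequate, light blue Abundant, blue Highly
#' Abundant — with structurally missing cells drawn uncolored. Exact hex
#' values are configurable; the defaults name the six conventional colors.
#'
#' @param colors named character vector over [equity_levels()].
#' @param annotate cell annotation mode: `"level"`, `"score"` or `"both"`.
#' @param missing_color fill for structurally missing cells.
#' @return object of class `equity_style`.
#' @export
equity_style <- function(colors = c("Absent" = "#d7191c",
                                    "Highly Inadequate" = "#f46d43",
                                    "Inadequate" = "#fdbf6f",
                                    "Adequate" = "#35978f",
                                    "Abundant" = "#abd9e9",
                                    "Highly Abundant" = "#2c7bb6"),
                         annotate = c("level", "score", "both"),
                         missing_color = "#ffffff") {
  annotate <- match.arg(annotate)
  if (!setequal(names(colors), equity_levels()))
    stop("colors must name exactly the six equity levels")
  if (anyDuplicated(colors)) stop("the six equity colors must be distinct")
  structure(list(colors = colors[equity_levels()], annotate = annotate,
                 missing_color = missing_color),
            class = "equity_style")
}

level_abbrev <- c("Absent" = "Abs", "Highly Inadequate" = "HI",
                  "Inadequate" = "Inad", "Adequate" = "Adeq",
                  "Abundant" = "Abun", "Highly Abundant" = "HA")

draw_equity_grid <- function(x, style) {
  df <- as.data.frame(x)
  df$rowlab <- if (all(is.na(df$conditioning))) df$subgroup else
    paste(df$subgroup, df$conditioning, sep = " | ")
  rows <- unique(df$rowlab)
  cols <- unique(df$outcome)
  nr <- length(rows); nc <- length(cols)
  op <- graphics::par(mar = c(1, 11, 6, 7), xpd = NA)
  on.exit(graphics::par(op))
  plot(NA, xlim = c(0, nc), ylim = c(0, nr), axes = FALSE, xlab = "", ylab = "",
       asp = NA)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cell <- df[df$rowlab == rows[i] & df$outcome == cols[j], ][1L, ]
    lev <- as.character(cell$level)
    fill <- if (is.na(lev)) style$missing_color else style$colors[[lev]]
    graphics::rect(j - 1, nr - i, j, nr - i + 1, col = fill, border = "grey40")
    lab <- switch(style$annotate,
      level = if (is.na(lev)) "" else level_abbrev[[lev]],
      score = if (is.na(cell$score)) "" else sprintf("%.2f", cell$score),
      both = if (is.na(lev)) "" else
        paste0(level_abbrev[[lev]],
               if (!is.na(cell$score) && is.finite(cell$score))
                 sprintf("\n%.2f", cell$score) else ""))
    graphics::text(j - 0.5, nr - i + 0.5, lab, cex = 0.7)
  }
  graphics::axis(2, at = seq_len(nr) - 0.5, labels = rev(rows), las = 2,
                 tick = FALSE, cex.axis = 0.8)
  graphics::axis(3, at = seq_len(nc) - 0.5, labels = cols, las = 2,
                 tick = FALSE, cex.axis = 0.8)
  graphics::legend("right", inset = -0.22, legend = names(style$colors),
                   fill = unname(style$colors), cex = 0.7, bty = "n")
  invisible(NULL)
}

#' Plot an equity table as a heatmap
#'
#' Rows are subgroup (by conditioning stratum where present), columns are
#' outcomes, colors follow the six-level legend of the style.
#'
#' @param x an `equity_table` from [equity_eval()].
#' @param style an [equity_style()].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.equity_table <- function(x, style = equity_style(), ...) {
  draw_equity_grid(x, style)
  invisible(x)
}

#' Render an equity heatmap to an image file with a sidecar table
#'
#' Writes the heatmap as PNG or SVG plus a machine-readable sidecar CSV of
#' exactly the cells drawn — figures are never the only record of a number.
#'
#' @param x an `equity_table`.
#' @param path image destination, ending `.png` or `.svg`.
#' @param style an [equity_style()].
#' @param width,height device size in pixels (PNG) or inches (SVG).
#' @return named vector with the image and sidecar paths, invisibly.
#' @export
render_heatmap <- function(x, path, style = equity_style(),
                           width = NULL, height = NULL) {
  stopifnot(inherits(x, "equity_table"), nrow(x) >= 1L)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = width %||% 900, height = height %||% 600)
  } else if (ext == "svg") {
    grDevices::svg(path, width = width %||% 10, height = height %||% 7)
  } else stop("path must end in .png or .svg")
  on.exit(grDevices::dev.off())
  draw_equity_grid(x, style)
  sidecar <- sub("\\.(png|svg)$", ".csv", path, ignore.case = TRUE)
  write_equity_table(x, csv_path = sidecar)
  invisible(c(image = path, sidecar = sidecar))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
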