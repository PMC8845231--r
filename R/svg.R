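# -- static SVG rendering of a chord model -----------------------------------

# 6-bin significance palette, bin 1 (least significant) -> bin 6
PBIN_COLORS <- c("#c6dbef", "#9ecae1", "#6baed6", "#4292c6", "#2171b5", "#084594")

polar <- function(cx, cy, r, theta) c(cx + r * cos(theta), cy + r * sin(theta))

arc_path <- function(cx, cy, r0, r1, a0, a1) {
  p1 <- polar(cx, cy, r1, a0); p2 <- polar(cx, cy, r1, a1)
  p3 <- polar(cx, cy, r0, a1); p4 <- polar(cx, cy, r0, a0)
  large <- if ((a1 - a0) > pi) 1 else 0
  sprintf(paste0("M %.2f %.2f A %.2f %.2f 0 %d 1 %.2f %.2f ",
                 "L %.2f %.2f A %.2f %.2f 0 %d 0 %.2f %.2f Z"),
          p1[1], p1[2], r1, r1, large, p2[1], p2[2],
          p3[1], p3[2], r0, r0, large, p4[1], p4[2])
}

truncate_label <- function(x, width = 60) {
  ifelse(nchar(x) > width, paste0(substr(x, 1, width - 1), "…"), x)
}

#' Render a chord model as a static SVG
#'
#' A non-interactive rendition of the diagram: arcs sized by gene count and
#' coloured by p-value bin, grey quadratic-curve ribbons for shared-gene
#' links, and outer merge-candidate arcs labelled with the pair similarity.
#' Labels are truncated at 60 characters. Byte-exactness is promised for
#' session JSON, not for images.
#'
#' @param model A `chord_model`.
#' @param file Output SVG path; omit to return the SVG lines.
#' @param size Canvas side length in pixels.
#' @return The SVG lines, invisibly when written to file.
#' @export
render_chord_svg <- function(model, file = NULL, size = 800) {
  stopifnot(inherits(model, "chord_model"))
  cx <- size / 2; cy <- size / 2
  r0 <- size * 0.32; r1 <- size * 0.38; r_merge <- size * 0.42
  gap <- 2 * pi * 0.006
  n <- length(model$arcs)
  span <- 2 * pi - n * gap

  a0 <- -pi / 2
  angles <- list()
  for (a in model$arcs) {
    a1 <- a0 + span * a$arc_fraction
    angles[[a$cluster_id]] <- c(a0, a1)
    a0 <- a1 + gap
  }

  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   size, size, size, size),
           sprintf('<rect width="%d" height="%d" fill="white"/>', size, size))

  for (l in model$links) {
    aa <- angles[[l$cluster_a]]; ab <- angles[[l$cluster_b]]
    p1 <- polar(cx, cy, r0, mean(aa)); p2 <- polar(cx, cy, r0, mean(ab))
    out <- c(out, sprintf(
      '<path d="M %.2f %.2f Q %.2f %.2f %.2f %.2f" stroke="#999999" stroke-width="%.2f" fill="none" opacity="0.6"/>',
      p1[1], p1[2], cx, cy, p2[1], p2[2],
      max(1, 6 * length(l$shared_genes) / max(1, length(model$arcs)))))
  }

  for (a in model$arcs) {
    ang <- angles[[a$cluster_id]]
    out <- c(out, sprintf('<path d="%s" fill="%s" stroke="#333333" stroke-width="0.5"/>',
                          arc_path(cx, cy, r0, r1, ang[1], ang[2]),
                          PBIN_COLORS[a$p_value_bin]))
    mid <- mean(ang)
    lp <- polar(cx, cy, r1 + size * 0.015, mid)
    anchor <- if (cos(mid) >= 0) "start" else "end"
    out <- c(out, sprintf(
      '<text x="%.2f" y="%.2f" font-size="%.1f" text-anchor="%s" font-family="sans-serif">%s</text>',
      lp[1], lp[2], size / 70, anchor,
      xml_escape(truncate_label(a$label))))
  }

  for (m in model$merge_arcs) {
    aa <- angles[[m$cluster_a]]; ab <- angles[[m$cluster_b]]
    out <- c(out, sprintf('<path d="%s" fill="#74c476" opacity="0.8"/>',
                          arc_path(cx, cy, r_merge, r_merge + size * 0.012,
                                   mean(aa), mean(ab))))
    mid <- (mean(aa) + mean(ab)) / 2
    lp <- polar(cx, cy, r_merge + size * 0.03, mid)
    out <- c(out, sprintf(
      '<text x="%.2f" y="%.2f" font-size="%.1f" text-anchor="middle" font-family="sans-serif" fill="#238b45">%s</text>',
      lp[1], lp[2], size / 80, format(round(m$similarity, 2))))
  }

  out <- c(out, "</svg>")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
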