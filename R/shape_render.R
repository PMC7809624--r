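# Reconstruction of landmark outlines from mode scores, and export of
# outline pairs / composite allele-effect shapes as TSV and SVG.

#' Reconstruct an outline from mode scores
#'
#' Inverse of the projection:
#' `outline = center + sum_k s_k * sd_k * mode_k` (the model center is
#' the average training shape in tangent coordinates; zero scores give it
#' back exactly), reshaped to the model's landmark layout. Reconstruction
#' is linear in the scores and, restricted to the model span, is the
#' exact inverse of [apply_shape_model()].
#'
#' @param model a `shape_model`.
#' @param scores numeric vector of length K (reference-SD units).
#' @param label,style stored on the outline (style `"solid"` or
#'   `"dashed"`, the line conventions used for reference vs displaced
#'   shapes).
#' @return object of class `outline`: list with `points` (P x 2 matrix),
#'   `label`, `style`.
#' @export
reconstruct_outline <- function(model, scores, label = "shape",
                                style = c("solid", "dashed")) {
  style <- match.arg(style)
  K <- ncol(model$modes)
  if (length(scores) != K)
    stop("scores must have length K = ", K, ", got ", length(scores))
  v <- model$center +
    as.vector(model$modes %*% (scores * model$mode_sds))
  structure(list(points = vec_to_points(v), label = label, style = style),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat("<outline>", x$label, "(", x$style, ") -", nrow(x$points), "points\n")
  invisible(x)
}

#' Outline pair at +/- c SD along one mode
#'
#' The conventional single-mode visualisation: the solid outline is the
#' shape at `+c` reference SDs on the chosen mode (all other modes zero),
#' the dashed outline at `-c` SDs. Default `c = 2`.
#'
#' @param model a `shape_model`.
#' @param hsm mode index.
#' @param c displacement in reference SDs.
#' @return list of two `outline`s: `plus` (solid) and `minus` (dashed).
#' @export
mode_outline_pair <- function(model, hsm, c = 2) {
  K <- ncol(model$modes)
  if (length(hsm) != 1L || hsm < 1L || hsm > K)
    stop("invalid mode index ", hsm, " (model has ", K, " modes)")
  s <- numeric(K)
  s[hsm] <- c
  list(plus = reconstruct_outline(model, s,
                                  label = sprintf("hsm%d_plus%gsd", hsm, c),
                                  style = "solid"),
       minus = reconstruct_outline(model, -s,
                                   label = sprintf("hsm%d_minus%gsd", hsm, c),
                                   style = "dashed"))
}

#' Composite per-allele shape effect
#'
#' Reconstructs the outline implied by a set of per-mode regression betas
#' (SD units per effect allele), each multiplied by an illustrative
#' `scale` (default 20, the conventional exaggeration for visualising
#' per-allele effects that would otherwise be invisibly small). The scale
#' is recorded on the returned outline so exaggerated shapes are never
#' mistaken for physical effect sizes.
#'
#' @param model a `shape_model`.
#' @param betas named numeric vector: names are mode indices (or
#'   `"hsm<k>"`), values per-allele betas. Duplicate modes are an error.
#' @param scale positive illustrative multiplier.
#' @param label outline label.
#' @return a dashed `outline` with attribute `"scale"`.
#' @export
composite_effect <- function(model, betas, scale = 20, label = "effect") {
  if (scale <= 0) stop("scale must be positive")
  idx <- names(betas)
  if (is.null(idx)) stop("betas must be named by mode index")
  idx <- as.integer(sub("^hsm", "", idx))
  K <- ncol(model$modes)
  if (anyNA(idx) || any(idx < 1L) || any(idx > K))
    stop("invalid mode index in betas")
  if (anyDuplicated(idx)) stop("duplicate mode indices in betas")
  s <- numeric(K)
  s[idx] <- scale * as.numeric(betas)
  out <- reconstruct_outline(model, s, label = label, style = "dashed")
  attr(out, "scale") <- scale
  out
}

#' Export outlines as SVG and TSV
#'
#' Writes an SVG with one polyline per outline (solid or dashed stroke per
#' the outline's style; y axis flipped so larger y is up) and a TSV of the
#' exact coordinates (`label`, `point_index`, `x`, `y`, `style`) with no
#' precision loss.
#'
#' @param outlines a single `outline` or list of them.
#' @param svg_path,tsv_path output paths (either may be NULL to skip).
#' @param width SVG canvas width in px (height follows the aspect ratio).
#' @return invisibly, a character vector of files written.
#' @export
export_outline <- function(outlines, svg_path = NULL, tsv_path = NULL,
                           width = 480) {
  if (inherits(outlines, "outline")) outlines <- list(outlines)
  stopifnot(all(vapply(outlines, inherits, logical(1), "outline")))
  written <- character(0)
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    writeLines("label\tpoint_index\tx\ty\tstyle", con)
    for (o in outlines)
      writeLines(paste(o$label, seq_len(nrow(o$points)),
                       num_full(o$points[, 1L]), num_full(o$points[, 2L]),
                       o$style, sep = "\t"), con)
    close(con)
    written <- c(written, tsv_path)
  }
  if (!is.null(svg_path)) {
    all_pts <- do.call(rbind, lapply(outlines, `[[`, "points"))
    rng_x <- range(all_pts[, 1L]); rng_y <- range(all_pts[, 2L])
    pad <- 0.05 * max(diff(rng_x), diff(rng_y), 1e-9)
    sc <- (width - 2) / (diff(rng_x) + 2 * pad)
    height <- ceiling((diff(rng_y) + 2 * pad) * sc) + 2
    lines <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
      as.integer(width), as.integer(height), as.integer(width),
      as.integer(height)))
    for (o in outlines) {
      px <- (o$points[, 1L] - rng_x[1L] + pad) * sc + 1
      py <- height - ((o$points[, 2L] - rng_y[1L] + pad) * sc + 1)
      dash <- if (o$style == "dashed") ' stroke-dasharray="6,4"' else ""
      lines <- c(lines, sprintf(
        '<polyline fill="none" stroke="black" stroke-width="1.5"%s points="%s"><title>%s</title></polyline>',
        dash, paste(sprintf("%.3f,%.3f", px, py), collapse = " "),
        o$label))
    }
    lines <- c(lines, "</svg>")
    writeLines(lines, svg_path)
    written <- c(written, svg_path)
  }
  invisible(written)
}

#' Read outlines back from an exported TSV
#' @param path TSV written by [export_outline()].
#' @return list of `outline` objects.
#' @export
read_outline_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$label, levels = unique(df$label))), function(d) {
    d <- d[order(d$point_index), ]
    structure(list(points = cbind(x = d$x, y = d$y), label = d$label[1L],
                   style = d$style[1L]), class = "outline")
  })
}
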