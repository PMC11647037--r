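# Attention extraction and group-differencing arithmetic.
#
# Holding every treatment factor fixed except one and subtracting the two
# groups' mean attention maps attributes the attention change to the varied
# factor (radiation dose/timing, or presence of anti-PD-L1).

#' Group-averaged attention map
#'
#' Runs the forward pass over every sample of one group's cohort and
#' averages the selected attention map element-wise. Averaging preserves
#' row-normalization over unmasked entries and exact zeros at masked
#' entries.
#'
#' @param model_params A trained `model_params` list.
#' @param cohort_samples List of `encoded_sample`s, all from one group.
#' @param which One of `"enc_self"` (radiation self-attention),
#'   `"dec_self"` (drug self-attention), `"cross"` (decoder-query to
#'   encoder-key attention; rows = drug steps, cols = radiation steps).
#' @param cfg A [model_config()].
#' @return A `group_attention` object: `group_id`, `which`, `map`
#'   (28 x 28), `n_samples`.
#' @export
group_attention <- function(model_params, cohort_samples,
                            which = c("cross", "enc_self", "dec_self"),
                            cfg = model_config()) {
  which <- match.arg(which)
  if (length(cohort_samples) == 0L) stop("empty cohort")
  gids <- unique(vapply(cohort_samples, function(s) s$group_id, character(1)))
  if (length(gids) != 1L) stop("mixed group_ids in cohort: ", toString(gids))
  acc <- NULL
  for (s in cohort_samples) {
    m <- forward(s, model_params, cfg)$maps[[which]]
    acc <- if (is.null(acc)) m else acc + m
  }
  structure(list(group_id = gids, which = which,
                 map = acc / length(cohort_samples),
                 n_samples = length(cohort_samples)),
            class = "group_attention")
}

#' @export
print.group_attention <- function(x, ...) {
  cat(sprintf("<group_attention> %s (%s), averaged over %d samples\n",
              x$group_id, x$which, x$n_samples))
  invisible(x)
}

#' Difference of two groups' mean attention maps
#'
#' Element-wise `a - b`. When the two groups differ in a single treatment
#' factor, the difference is attributable to that factor alone. The result
#' is antisymmetric under operand swap and bounded in `[-1, 1]`.
#'
#' @param a,b `group_attention` objects of the same map kind.
#' @return A `difference_map`: `minuend_group`, `subtrahend_group`,
#'   `which`, `matrix` (28 x 28).
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "group_attention"), inherits(b, "group_attention"))
  if (a$which != b$which) stop("cannot difference maps of different kinds: ",
                               a$which, " vs ", b$which)
  if (!all(dim(a$map) == dim(b$map))) stop("map shape mismatch")
  structure(list(minuend_group = a$group_id, subtrahend_group = b$group_id,
                 which = a$which, matrix = a$map - b$map),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  pk <- peak_locator(x)
  cat(sprintf("<difference_map> %s - %s (%s); peak %+.4g at row %d, col %d\n",
              x$minuend_group, x$subtrahend_group, x$which,
              pk$value, pk$row, pk$col))
  invisible(x)
}

#' Locate the dominant entry of a difference map
#'
#' Arg-max of the absolute value with deterministic tie-breaking (lowest
#' row, then lowest column). Rows and columns are 1-based step indices;
#' `day_row`/`day_col` give the corresponding day labels relative to the
#' first pulse.
#'
#' @param map A `difference_map` (or bare numeric matrix).
#' @return List with `row`, `col`, `value`, `day_row`, `day_col`.
#' @export
peak_locator <- function(map) {
  m <- if (inherits(map, "difference_map")) map$matrix else map
  if (length(m) == 0L) stop("empty map")
  best <- max(abs(m))
  # column-major scan ordered by (row, col): scan rows within transposed matrix
  tm <- t(m)
  hit <- which(abs(as.vector(tm)) == best)[1]
  row <- ((hit - 1L) %/% ncol(m)) + 1L
  col <- ((hit - 1L) %% ncol(m)) + 1L
  list(row = as.integer(row), col = as.integer(col), value = m[row, col],
       day_row = as.integer(row) - 4L, day_col = as.integer(col) - 4L)
}

#' Export a map as a day-labeled CSV matrix
#'
#' @param x A `group_attention` or `difference_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attention_csv <- function(x, path) {
  m <- if (inherits(x, "difference_map")) x$matrix else x$map
  days <- seq_len(nrow(m)) - 4L
  df <- as.data.frame(m)
  names(df) <- paste0("day_", days)
  df <- cbind(day = days, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render attention or difference maps as heatmap images
#'
#' Group maps use a sequential fill from 0; difference maps use a diverging
#' scale centered at 0. The causally masked (future) upper triangle is
#' drawn in a neutral shade. Day axes are labeled relative to the first
#' pulse.
#'
#' @param maps A `group_attention`, a `difference_map`, or a list of them.
#' @param out_path Output directory (created if missing).
#' @param width,height,dpi Image geometry passed to the PNG device.
#' @return Character vector of written file paths.
#' @export
render_heatmaps <- function(maps, out_path, width = 5, height = 4.4, dpi = 150) {
  if (inherits(maps, "group_attention") || inherits(maps, "difference_map")) {
    maps <- list(maps)
  }
  dir.create(out_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_path)) stop("cannot create output directory: ", out_path)
  vapply(maps, function(x) {
    is_diff <- inherits(x, "difference_map")
    m <- if (is_diff) x$matrix else x$map
    n <- nrow(m)
    df <- expand.grid(col = seq_len(n), row = seq_len(n))
    df$value <- as.vector(t(m))
    df$masked <- df$col > df$row
    df$day_row <- df$row - 4L
    df$day_col <- df$col - 4L
    ttl <- if (is_diff) sprintf("%s - %s (%s)", x$minuend_group, x$subtrahend_group, x$which)
           else sprintf("%s (%s)", x$group_id, x$which)
    g <- ggplot2::ggplot(df, ggplot2::aes(x = day_col, y = day_row)) +
      ggplot2::geom_tile(data = df[df$masked, ], fill = "grey92") +
      ggplot2::geom_tile(data = df[!df$masked, ], ggplot2::aes(fill = value)) +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(title = ttl,
                    x = "key step (day rel. first pulse)",
                    y = "query step (day rel. first pulse)",
                    fill = if (is_diff) "Δ attention" else "attention") +
      ggplot2::theme_minimal(base_size = 9)
    g <- if (is_diff) {
      lim <- max(abs(m), 1e-12)
      g + ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                        high = "#B2182B", limits = c(-lim, lim))
    } else {
      g + ggplot2::scale_fill_gradient(low = "white", high = "#B2182B",
                                       limits = c(0, max(m, 1e-12)))
    }
    fname <- if (is_diff) sprintf("diff_%s_minus_%s_%s.png", x$minuend_group,
                                  x$subtrahend_group, x$which)
             else sprintf("attention_%s_%s.png", x$group_id, x$which)
    fpath <- file.path(out_path, fname)
    grDevices::png(fpath, width = width * dpi, height = height * dpi, res = dpi,
                   type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE)
    print(g)
    fpath
  }, character(1))
}

#' Difference-map report as JSON
#'
#' Records the operands, map kind, peak location (1-based steps and day
#' labels), peak value, and summed absolute difference.
#'
#' @param dmap A `difference_map`.
#' @param path Output JSON path.
#' @return The report list, invisibly.
#' @export
write_difference_report <- function(dmap, path) {
  pk <- peak_locator(dmap)
  rep <- list(minuend_group = dmap$minuend_group,
              subtrahend_group = dmap$subtrahend_group,
              which = dmap$which,
              peak = pk,
              sum_abs_difference = sum(abs(dmap$matrix)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
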