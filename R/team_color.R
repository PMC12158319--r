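#' Team jersey palette
#'
#' Reference jersey colors for the two teams plus the thresholds of the
#' two-stage classifier. Matching happens in CIELAB: stage 1 assigns the
#' nearer reference color when its perceptual distance (Euclidean Delta-E in
#' Lab) is within `match_threshold`; stage 2, the fallback for colors that
#' match neither reference, splits on lightness, sending colors with L*
#' above `lightness_split` to the lighter team, below to the darker team,
#' and leaving colors inside the `lightness_band` dead band as `unknown`.
#'
#' The defaults mirror a white (Team A, light) versus navy (Team B, dark)
#' uniform pairing. The two references must differ by more than twice the
#' match threshold so that stage-1 assignments can never be ambiguous.
#'
#' @param team_a_ref,team_b_ref RGB triples in 0..255.
#' @param match_threshold Stage-1 Delta-E gate.
#' @param labels Team labels, `c("A", "B")`.
#' @param lightness_split Stage-2 L* split point.
#' @param lightness_band Half-width of the stage-2 dead band.
#' @param min_pixels Observations with fewer mask-support pixels than this
#'   are classified `unknown` (tiny crops carry unreliable color).
#' @return Object of class `team_palette`.
#' @export
team_palette <- function(team_a_ref = c(255, 255, 255),
                         team_b_ref = c(0, 0, 128),
                         match_threshold = 25,
                         labels = c("A", "B"),
                         lightness_split = 50,
                         lightness_band = 5,
                         min_pixels = 25) {
  stopifnot(length(team_a_ref) == 3L, length(team_b_ref) == 3L,
            length(labels) == 2L)
  if (match_threshold <= 0) cg_stop("team_palette: match_threshold must be > 0")
  sep <- delta_e(rgb255_to_lab(rbind(team_a_ref))[1, ],
                 rgb255_to_lab(rbind(team_b_ref))[1, ])
  if (sep <= 2 * match_threshold) {
    cg_stop(paste0("team_palette: reference colors are too similar ",
                   "(Delta-E %.1f <= 2 x threshold %.1f); teams must wear ",
                   "distinctly different colors"), sep, match_threshold)
  }
  structure(list(team_a_ref = as.numeric(team_a_ref),
                 team_b_ref = as.numeric(team_b_ref),
                 match_threshold = match_threshold,
                 labels = as.character(labels),
                 lightness_split = lightness_split,
                 lightness_band = lightness_band,
                 min_pixels = min_pixels),
            class = "team_palette")
}

#' Read / write a palette as YAML
#'
#' @param path YAML file with keys `team_a`, `team_b` (each `label`, `rgb`),
#'   and optional `match_threshold`, `lightness_split`, `lightness_band`,
#'   `min_pixels`. A white/navy default ships with the package under
#'   `system.file("extdata", "palette_default.yaml", package = "courtgaze")`.
#' @return A `team_palette`.
#' @export
read_palette <- function(path) {
  if (!file.exists(path)) cg_stop("palette file not found: %s", path)
  y <- yaml::read_yaml(path)
  team_palette(team_a_ref = unlist(y$team_a$rgb),
               team_b_ref = unlist(y$team_b$rgb),
               match_threshold = y$match_threshold %||% 25,
               labels = c(y$team_a$label %||% "A", y$team_b$label %||% "B"),
               lightness_split = y$lightness_split %||% 50,
               lightness_band = y$lightness_band %||% 5,
               min_pixels = y$min_pixels %||% 25)
}

#' @rdname read_palette
#' @param palette A `team_palette`.
#' @export
write_palette <- function(palette, path) {
  yaml::write_yaml(list(
    team_a = list(label = palette$labels[[1]], rgb = palette$team_a_ref),
    team_b = list(label = palette$labels[[2]], rgb = palette$team_b_ref),
    match_threshold = palette$match_threshold,
    lightness_split = palette$lightness_split,
    lightness_band = palette$lightness_band,
    min_pixels = palette$min_pixels), path)
  invisible(path)
}

#' Convert sRGB (0..255) to CIELAB
#' @param m Matrix with one RGB triple per row, values in 0..255.
#' @return Matrix of Lab rows (D65 white point).
#' @export
rgb255_to_lab <- function(m) {
  m <- rbind(m)
  grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")
}

#' Euclidean Delta-E*ab between two Lab colors
#' @param lab1,lab2 Length-3 Lab vectors.
#' @export
delta_e <- function(lab1, lab2) sqrt(sum((lab1 - lab2)^2))

#' Dominant color of a masked clothing crop
#'
#' The dominant color is the channel-wise median over mask-support pixels
#' only; the zeros outside the mask never contribute. The median is robust
#' to jersey numbers and trim occupying a minority of the clothing area.
#'
#' @param masked_patch Image array (h x w x 3) in `[0, 1]` (masked or raw
#'   crop; only support pixels are read).
#' @param mask Binary matrix (h x w); support must be non-empty.
#' @param frame_index Optional ordinal recorded in the observation.
#' @return List of class `color_observation`: `dominant` (RGB 0..255),
#'   `n_pixels`, `frame_index`.
#' @export
extract_dominant_color <- function(masked_patch, mask, frame_index = NA_integer_) {
  if (!all(dim(mask) == dim(masked_patch)[1:2])) {
    cg_stop("extract_dominant_color: mask/patch dimension mismatch")
  }
  sup <- which(mask == 1L)
  if (length(sup) == 0L) cg_stop("no clothing pixels (empty mask support)")
  px <- vapply(1:3, function(ch) {
    stats::median(masked_patch[, , ch][sup])
  }, numeric(1))
  structure(list(dominant = px * 255, n_pixels = length(sup),
                 frame_index = frame_index),
            class = "color_observation")
}

# classify one RGB triple (0..255); internal vectorizable core
classify_color <- function(rgb, palette) {
  if (any(!is.finite(rgb))) return("unknown")
  labs <- rgb255_to_lab(rbind(rgb, palette$team_a_ref, palette$team_b_ref))
  d_a <- delta_e(labs[1, ], labs[2, ])
  d_b <- delta_e(labs[1, ], labs[3, ])
  # stage 1: nearest known reference within the Delta-E gate
  if (min(d_a, d_b) <= palette$match_threshold) {
    return(palette$labels[[if (d_a <= d_b) 1L else 2L]])
  }
  # stage 2 fallback: light-versus-dark lightness split with a dead band
  L <- labs[1, 1]
  if (abs(L - palette$lightness_split) <= palette$lightness_band) {
    return("unknown")
  }
  light_team <- palette$labels[[if (labs[2, 1] >= labs[3, 1]) 1L else 2L]]
  dark_team <- setdiff(palette$labels, light_team)[[1L]]
  if (L > palette$lightness_split) light_team else dark_team
}

#' Classify a color observation as Team A, Team B, or unknown
#'
#' Two-stage rule (see [team_palette()]): a Delta-E match against the known
#' reference colors, then a light/dark lightness fallback for colors that
#' match neither. Observations supported by fewer than `min_pixels` pixels
#' are returned as `unknown` regardless of color.
#'
#' @param obs A `color_observation` from [extract_dominant_color()].
#' @param palette A [team_palette()].
#' @return One of `palette$labels` or `"unknown"`.
#' @export
classify_team <- function(obs, palette) {
  if (obs$n_pixels < palette$min_pixels) return("unknown")
  classify_color(obs$dominant, palette)
}

#' Calibrate a palette from labeled sample patches
#'
#' Builds team reference colors as the per-team median of dominant colors
#' over labeled masked patches (at least one patch per team); thresholds are
#' taken from `template`.
#'
#' @param samples List of lists with elements `patch` (h x w x 3 array),
#'   `mask` (binary matrix) and `team` (a label in `template$labels`).
#' @param template A `team_palette` supplying thresholds and labels.
#' @return A calibrated `team_palette`.
#' @export
calibrate_palette <- function(samples, template = team_palette()) {
  doms <- lapply(samples, function(s) {
    obs <- extract_dominant_color(s$patch, s$mask)
    list(team = s$team, dominant = obs$dominant)
  })
  teams <- vapply(doms, `[[`, character(1), "team")
  refs <- lapply(template$labels, function(lb) {
    sel <- doms[teams == lb]
    if (length(sel) == 0L) cg_stop("calibrate_palette: no samples for team %s", lb)
    apply(do.call(rbind, lapply(sel, `[[`, "dominant")), 2, stats::median)
  })
  team_palette(team_a_ref = refs[[1]], team_b_ref = refs[[2]],
               match_threshold = template$match_threshold,
               labels = template$labels,
               lightness_split = template$lightness_split,
               lightness_band = template$lightness_band,
               min_pixels = template$min_pixels)
}
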