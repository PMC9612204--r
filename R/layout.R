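#' Electrode layouts on the unit sphere
#'
#' An `eeg_layout` is a tibble with one row per electrode and columns
#' `label`, `x`, `y`, `z`. Positions are unit vectors on a spherical head
#' model (x = right ear, y = nasion, z = vertex); all geometry downstream
#' (spline interpolation, topographic projection) is radius-independent.
#'
#' @param df data frame with columns `label`, `x`, `y`, `z`.
#' @param name human-readable layout name.
#' @param kind one of `"ten_twenty"`, `"equidistant"`, `"combined"`,
#'   `"custom"`.
#' @return a tibble of class `eeg_layout` with attributes `layout_name` and
#'   `layout_kind`.
#' @export
eeg_layout <- function(df, name = "custom", kind = "custom") {
  stopifnot(is.data.frame(df))
  needed <- c("label", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("layout is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df[needed])
  out$label <- as.character(out$label)
  norms <- sqrt(out$x^2 + out$y^2 + out$z^2)
  bad <- which(!is.finite(norms) | norms < 1e-12)
  if (length(bad) > 0) {
    stop("zero-norm or non-finite electrode position in row ", bad[1],
         " (label '", out$label[bad[1]], "')", call. = FALSE)
  }
  out$x <- out$x / norms
  out$y <- out$y / norms
  out$z <- out$z / norms
  validate_layout(out)
  structure(out,
            layout_name = name,
            layout_kind = kind,
            class = c("eeg_layout", class(tibble::tibble())))
}

validate_layout <- function(df) {
  if (any(!nzchar(df$label))) stop("empty electrode label", call. = FALSE)
  dup <- df$label[duplicated(df$label)]
  if (length(dup) > 0) {
    stop("duplicate electrode label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  pos <- layout_positions(df)
  if (nrow(pos) > 1) {
    # pairwise angular separation; layouts are small so O(n^2) is fine
    gram <- pos %*% t(pos)
    gram[gram > 1] <- 1
    gram[gram < -1] <- -1
    ang <- acos(gram)
    diag(ang) <- Inf
    if (min(ang) < 1e-6) {
      idx <- which(ang == min(ang), arr.ind = TRUE)[1, ]
      stop("electrodes '", df$label[idx[1]], "' and '", df$label[idx[2]],
           "' are closer than 1e-6 radians", call. = FALSE)
    }
  }
  invisible(df)
}

#' Extract electrode positions as a numeric matrix
#'
#' @param layout an `eeg_layout` (or any data frame with x, y, z columns).
#' @return n x 3 matrix of unit vectors, rownames = labels.
#' @export
layout_positions <- function(layout) {
  m <- cbind(layout$x, layout$y, layout$z)
  rownames(m) <- layout$label
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat(sprintf("<eeg_layout '%s' (%s), %d electrodes>\n",
              attr(x, "layout_name"), attr(x, "layout_kind"), nrow(x)))
  NextMethod()
}

#' Angular distance between two points on the unit sphere
#'
#' @param p,q unit 3-vectors.
#' @return angle in radians, in \[0, pi\].
#' @export
angular_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 3, length(q) == 3)
  if (abs(sum(p^2) - 1) > 1e-6 || abs(sum(q^2) - 1) > 1e-6) {
    stop("angular_distance() expects unit vectors", call. = FALSE)
  }
  acos(max(-1, min(1, sum(p * q))))
}

# spherical linear interpolation between unit vectors (used to lay out the
# intermediate ten-twenty rows along great-circle arcs)
slerp <- function(a, b, t) {
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - t) * omega) * a + sin(t * omega) * b) / sin(omega)
}

# unit vector from inclination theta (radians from vertex +z) and azimuth phi
# (radians from nasion +y, positive toward the LEFT ear, i.e. counterclockwise
# seen from above with -x = left)
sph_vec <- function(theta, phi) {
  c(x = -sin(theta) * sin(phi), y = sin(theta) * cos(phi), z = cos(theta))
}

#' Built-in 64-channel electrode layouts
#'
#' `"ten_twenty"` is the extended international ten-twenty (10-10 subset)
#' layout: midline sites at 18-degree steps from the vertex, the standard
#' circumferential ring at 72 degrees inclination, intermediate rows placed by
#' great-circle interpolation between the midline and ring site of each row,
#' plus mastoids M1/M2. `"equidistant"` is a quasi-uniform covering of the
#' upper spherical cap by concentric rings with uniform polar spacing;
#' lateral pairs are numbered sequentially from the frontmost pair of the
#' outermost ring, so `1L`/`1R` sit over the forehead (the equidistant
#' counterpart of Fp1/Fp2); midline sites are numbered `<n>Z`.
#'
#' @param kind `"ten_twenty"` or `"equidistant"`.
#' @return a 64-electrode `eeg_layout`.
#' @export
builtin_layout <- function(kind = c("ten_twenty", "equidistant")) {
  if (!is.character(kind) || length(kind) != 1 ||
      !kind %in% c("ten_twenty", "equidistant")) {
    stop("unknown layout kind: ",
         paste(utils::head(as.character(kind), 1), collapse = ""),
         " (expected 'ten_twenty' or 'equidistant')", call. = FALSE)
  }
  if (kind == "ten_twenty") layout_ten_twenty() else layout_equidistant()
}

layout_ten_twenty <- function() {
  d18 <- pi / 10 * 1.8  # 18 degrees
  deg <- function(d) d * pi / 180
  rows <- list()
  add <- function(label, v) rows[[length(rows) + 1]] <<-
      tibble::tibble(label = label, x = v[1], y = v[2], z = v[3])

  # midline: vertex to front/back at 18-degree steps
  midline <- list(Fpz = sph_vec(deg(72), 0), Fz = sph_vec(deg(36), 0),
                  FCz = sph_vec(deg(18), 0), Cz = sph_vec(0, 0),
                  CPz = sph_vec(deg(18), pi), Pz = sph_vec(deg(36), pi),
                  POz = sph_vec(deg(54), pi), Oz = sph_vec(deg(72), pi))
  for (nm in names(midline)) add(nm, midline[[nm]])

  # circumferential ring at 72 degrees inclination, azimuth from nasion
  ring <- function(az_deg, left, right) {
    add(left, sph_vec(deg(72), deg(az_deg)))
    add(right, sph_vec(deg(72), -deg(az_deg)))
  }
  ring(18, "Fp1", "Fp2"); ring(36, "AF7", "AF8"); ring(54, "F7", "F8")
  ring(72, "FT7", "FT8"); ring(90, "T7", "T8"); ring(108, "TP7", "TP8")
  ring(126, "P7", "P8"); ring(144, "PO7", "PO8"); ring(162, "O1", "O2")

  # intermediate rows: fractions along the great-circle arc midline -> ring
  row_arc <- function(mid, ringL, labelsL, labelsR, fracs) {
    a <- midline[[mid]]
    bL <- sph_vec(deg(72), deg(ringL))
    bR <- sph_vec(deg(72), -deg(ringL))
    for (i in seq_along(fracs)) {
      add(labelsL[i], slerp(a, bL, fracs[i]))
      add(labelsR[i], slerp(a, bR, fracs[i]))
    }
  }
  row_arc("Fz", 54, c("F1", "F3", "F5"), c("F2", "F4", "F6"), c(1, 2, 3) / 4)
  row_arc("FCz", 72, c("FC1", "FC3", "FC5"), c("FC2", "FC4", "FC6"),
          c(1, 2, 3) / 4)
  row_arc("Cz", 90, c("C1", "C3", "C5"), c("C2", "C4", "C6"), c(1, 2, 3) / 4)
  row_arc("CPz", 108, c("CP1", "CP3", "CP5"), c("CP2", "CP4", "CP6"),
          c(1, 2, 3) / 4)
  row_arc("Pz", 126, c("P1", "P3", "P5"), c("P2", "P4", "P6"), c(1, 2, 3) / 4)
  # AF row: arc anchored on the (unoccupied) AFz midline point
  afz <- sph_vec(deg(54), 0)
  add("AF3", slerp(afz, sph_vec(deg(72), deg(36)), 1 / 2))
  add("AF4", slerp(afz, sph_vec(deg(72), -deg(36)), 1 / 2))
  row_arc("POz", 144, c("PO3", "PO5"), c("PO4", "PO6"), c(1, 2) / 3)

  # mastoids, below the ring behind the ears
  add("M1", sph_vec(deg(105), deg(108)))
  add("M2", sph_vec(deg(105), -deg(108)))

  df <- dplyr::bind_rows(rows)
  eeg_layout(df, name = "extended ten-twenty (64)", kind = "ten_twenty")
}

layout_equidistant <- function() {
  deg <- function(d) d * pi / 180
  # concentric rings, uniform 18-degree polar spacing, counts ~ sin(theta);
  # rings sit at 9-degree offsets from the ten-twenty grid so the combined
  # 128-channel montage has no coincident positions
  rings <- list(list(theta = 81, n = 20), list(theta = 63, n = 18),
                list(theta = 45, n = 14), list(theta = 27, n = 9),
                list(theta = 9, n = 3))
  rows <- list()
  pair_i <- 0L
  mid_i <- 0L
  for (rg in rings) {
    n <- rg$n
    th <- deg(rg$theta)
    if (n %% 2 == 1) {
      # odd ring: one front-midline site plus (n-1)/2 lateral pairs
      mid_i <- mid_i + 1L
      v <- sph_vec(th, 0)
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = paste0(mid_i, "Z"), x = v[1], y = v[2], z = v[3])
      azs <- (seq_len((n - 1) / 2)) * 360 / n
    } else {
      # even ring: pairs straddle the midline at half-step offsets
      azs <- (seq_len(n / 2) - 0.5) * 360 / n
    }
    for (az in azs) {
      pair_i <- pair_i + 1L
      vl <- sph_vec(th, deg(az))
      vr <- sph_vec(th, -deg(az))
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = paste0(pair_i, "L"), x = vl[1], y = vl[2], z = vl[3])
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = paste0(pair_i, "R"), x = vr[1], y = vr[2], z = vr[3])
    }
  }
  df <- dplyr::bind_rows(rows)
  stopifnot(nrow(df) == 64)
  eeg_layout(df, name = "equidistant (64)", kind = "equidistant")
}

#' Combine two layouts by label union
#'
#' Electrodes sharing a label must agree in position (within 1e-6 radians)
#' and appear once; the result keeps `a`'s electrodes first, then `b`'s novel
#' electrodes. Combining the two built-in 64-channel layouts yields the
#' 128-position montage every recording is interpolated to.
#'
#' @param a,b `eeg_layout` objects.
#' @param name name for the combined layout.
#' @return an `eeg_layout` of kind `"combined"`.
#' @export
combined_layout <- function(a, b, name = "combined") {
  shared <- intersect(a$label, b$label)
  for (lbl in shared) {
    pa <- as.numeric(a[a$label == lbl, c("x", "y", "z")])
    pb <- as.numeric(b[b$label == lbl, c("x", "y", "z")])
    if (angular_distance(pa, pb) > 1e-6) {
      stop("label '", lbl, "' has conflicting positions in the two layouts",
           call. = FALSE)
    }
  }
  novel <- b[!b$label %in% shared, ]
  df <- dplyr::bind_rows(tibble::as_tibble(a)[, c("label", "x", "y", "z")],
                         tibble::as_tibble(novel)[, c("label", "x", "y", "z")])
  eeg_layout(df, name = name, kind = "combined")
}

#' Read / write electrode layouts as BIDS-style electrodes.tsv
#'
#' Tab-separated with header `name x y z`; positions are renormalized to unit
#' length on load, row order preserved. The writer emits 9-significant-digit
#' coordinates.
#'
#' @param path file path.
#' @param name,kind passed to [eeg_layout()].
#' @return `load_layout()` returns an `eeg_layout`; `save_layout()` returns
#'   `path` invisibly.
#' @export
load_layout <- function(path, name = basename(path), kind = "custom") {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("name", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("electrodes file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("x", "y", "z")) {
    if (!is.numeric(df[[col]])) {
      stop("non-numeric coordinate in column '", col, "' of '", path, "'",
           call. = FALSE)
    }
  }
  norms <- sqrt(df$x^2 + df$y^2 + df$z^2)
  if (any(!is.finite(norms) | norms < 1e-12)) {
    stop("zero-norm position at row ", which(norms < 1e-12)[1], " of '",
         path, "'", call. = FALSE)
  }
  eeg_layout(tibble::tibble(label = df$name, x = df$x, y = df$y, z = df$z),
             name = name, kind = kind)
}

#' @rdname load_layout
#' @param layout an `eeg_layout` to write.
#' @export
save_layout <- function(layout, path) {
  df <- data.frame(name = layout$label,
                   x = formatC(layout$x, format = "g", digits = 9),
                   y = formatC(layout$y, format = "g", digits = 9),
                   z = formatC(layout$z, format = "g", digits = 9))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# nearest-neighbour angular distances within a layout (quasi-uniformity QC)
nn_angles <- function(layout) {
  pos <- layout_positions(layout)
  gram <- pos %*% t(pos)
  gram[gram > 1] <- 1; gram[gram < -1] <- -1
  ang <- acos(gram)
  diag(ang) <- Inf
  apply(ang, 1, min)
}
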