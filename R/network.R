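#' Skeletonize a binary image (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels from the foreground until a one-pixel-
#' wide, 8-connected medial skeleton remains, using the classic two-subiteration
#' Zhang-Suen scheme. Input and output are logical matrices
#' (`TRUE` = foreground).
#'
#' @param img Logical (or 0/1 numeric) matrix.
#' @return Logical matrix of the same dimensions containing the skeleton.
#' @examples
#' img <- matrix(FALSE, 9, 9); img[4:6, 2:8] <- TRUE
#' sum(skeletonize_image(img))
#' @export
skeletonize_image <- function(img) {
  if (is.numeric(img)) img <- img != 0
  stopifnot(is.logical(img), is.matrix(img), length(img) > 0)
  nr <- nrow(img); nc <- ncol(img)
  # pad to avoid border checks
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- img
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- (1 + max(0, dr)):(nrow(m) + min(0, dr))
    cs <- (1 + max(0, dc)):(ncol(m) + min(0, dc))
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours in the conventional order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      nb <- list(
        shift(p, -1, 0), shift(p, -1, 1), shift(p, 0, 1), shift(p, 1, 1),
        shift(p, 1, 0), shift(p, 1, -1), shift(p, 0, -1), shift(p, -1, -1)
      )
      bsum <- Reduce(`+`, nb)
      a <- matrix(0L, nrow(p), ncol(p))
      for (k in 1:8) {
        nxt <- nb[[if (k == 8) 1 else k + 1]]
        a <- a + (!nb[[k]] & nxt)
      }
      if (phase == 1) {
        cond <- !nb[[1]] | !nb[[3]] | !nb[[5]]   # P2 P4 P6
        cond2 <- !nb[[3]] | !nb[[5]] | !nb[[7]]  # P4 P6 P8
      } else {
        cond <- !nb[[1]] | !nb[[3]] | !nb[[7]]   # P2 P4 P8
        cond2 <- !nb[[1]] | !nb[[5]] | !nb[[7]]  # P2 P6 P8
      }
      kill <- p & bsum >= 2 & bsum <= 6 & a == 1 & cond & cond2
      if (any(kill)) {
        p[kill] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nr + 1), 2:(nc + 1)]
}

neighbour_counts <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- skel
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + p[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  acc
}

# 8-connected component labelling by flood fill (images here are small masks)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask)
  nr <- nrow(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0) {
      s <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (s - 1L) %% nr + 1L
      c <- (s - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || cc < 1 || rr > nr || cc > ncol(mask)) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
  }
  lab
}

#' Graph decomposition of a skeleton
#'
#' Classifies skeleton pixels by their 8-neighbour count: endpoints have one
#' neighbour, junction pixels three or more. Adjacent junction pixels are
#' merged into single junction clusters (a thick crossing counts once).
#' Branches are the connected runs of ordinary skeleton pixels between
#' nodes; each branch length sums the pixel-to-pixel steps along its path (1
#' per axial step, sqrt(2) per diagonal) plus the step joining each branch
#' end to its adjacent node, scaled by `pixel_size`.
#'
#' @param skel Logical skeleton matrix (see [skeletonize_image()]).
#' @param pixel_size Physical pixel size in micrometres (default 1).
#' @return A list with `n_junctions`, `n_endpoints`, `branches` (tibble of
#'   `branch`, `length_um`), `total_length_um`, `avg_length_um`,
#'   `n_skeleton_px`.
#' @export
skeleton_graph <- function(skel, pixel_size = 1) {
  if (is.numeric(skel)) skel <- skel != 0
  stopifnot(is.logical(skel), is.matrix(skel), pixel_size > 0)
  if (!any(skel)) {
    return(list(n_junctions = 0L, n_endpoints = 0L,
                branches = tibble::tibble(branch = integer(0), length_um = double(0)),
                total_length_um = 0, avg_length_um = NA_real_,
                n_skeleton_px = 0L))
  }
  nb <- neighbour_counts(skel)
  junction_px <- skel & nb >= 3
  endpoint_px <- skel & nb == 1
  jlab <- label_components(junction_px)
  n_junctions <- max(jlab)
  # branches: components of the skeleton with junction pixels removed
  body <- skel & !junction_px
  blab <- label_components(body)
  nbr <- max(blab)
  nr <- nrow(skel)
  step_len <- function(i, j) {
    dr <- abs((i - 1L) %% nr - (j - 1L) %% nr)
    dc <- abs((i - 1L) %/% nr - (j - 1L) %/% nr)
    if (dr + dc == 2L && dr == 1L) sqrt(2) else 1
  }
  path_length <- function(cells) {
    # cells form a simple path or cycle (any pixel with >= 3 skeleton
    # neighbours was removed as a junction); trace it end to end
    if (length(cells) <= 1) return(0)
    rs <- (cells - 1L) %% nr + 1L
    cs <- (cells - 1L) %/% nr + 1L
    adj <- function(i, j) i != j && abs(rs[i] - rs[j]) <= 1 && abs(cs[i] - cs[j]) <= 1
    deg <- purrr::map_int(seq_along(cells), function(i) {
      sum(purrr::map_lgl(seq_along(cells), function(j) adj(i, j)))
    })
    start <- if (any(deg <= 1)) which(deg <= 1)[1] else 1L
    visited <- rep(FALSE, length(cells))
    cur <- start
    visited[cur] <- TRUE
    total <- 0
    repeat {
      nxt <- which(!visited & purrr::map_lgl(seq_along(cells), function(j) adj(cur, j)))
      if (length(nxt) == 0) break
      # prefer axial neighbours so diagonal shortcuts at corners are not taken
      steps <- purrr::map_dbl(nxt, function(j) step_len(cells[cur], cells[j]))
      j <- nxt[which.min(steps)]
      total <- total + step_len(cells[cur], cells[j])
      visited[j] <- TRUE
      cur <- j
    }
    if (all(deg >= 2) && adj(cur, start)) {
      total <- total + step_len(cells[cur], cells[start])  # close the cycle
    }
    total
  }
  jcells <- which(junction_px)
  branch_len <- double(nbr)
  for (b in seq_len(nbr)) {
    cells <- which(blab == b)
    len <- path_length(cells)
    # connection steps to adjacent junction clusters (count each touching
    # cluster once, from the nearest branch cell)
    if (length(jcells) > 0) {
      rs <- (cells - 1L) %% nr + 1L
      cs <- (cells - 1L) %/% nr + 1L
      touched <- integer(0)
      best <- list()
      for (jc in jcells) {
        jr <- (jc - 1L) %% nr + 1L
        jcc <- (jc - 1L) %/% nr + 1L
        hit <- which(abs(rs - jr) <= 1 & abs(cs - jcc) <= 1)
        if (length(hit) > 0) {
          cl <- jlab[jc]
          d <- min(purrr::map_dbl(cells[hit], function(x) step_len(x, jc)))
          if (!cl %in% touched || d < best[[as.character(cl)]]) {
            touched <- union(touched, cl)
            best[[as.character(cl)]] <- d
          }
        }
      }
      len <- len + sum(unlist(best))
    }
    branch_len[b] <- len
  }
  branches <- tibble::tibble(branch = seq_len(nbr),
                             length_um = branch_len * pixel_size)
  total <- sum(branches$length_um)
  list(
    n_junctions = as.integer(n_junctions),
    n_endpoints = as.integer(sum(endpoint_px)),
    branches = branches,
    total_length_um = total,
    avg_length_um = if (nbr > 0) total / nbr else NA_real_,
    n_skeleton_px = as.integer(sum(skel))
  )
}

#' Gliding-box lacunarity of a binary image
#'
#' For each box size `r`, slides an `r x r` window over every fully
#' contained position, counts foreground pixels `m`, and computes
#' `Lambda(r) = E[m^2] / E[m]^2`; the reported lacunarity is the mean of
#' `Lambda(r)` over the box-size set (default `{2, 4, 8, 16, 32}`, truncated
#' to sizes that fit the image). A translation-invariant full image has
#' lacunarity exactly 1; gappier, more heterogeneous patterns score higher.
#'
#' @param img Logical (or 0/1) matrix.
#' @param box_sizes Integer vector of box edge lengths.
#' @param aggregate If `TRUE` (default) return the mean over box sizes;
#'   otherwise a tibble of `r`, `lambda`.
#' @return Scalar lacunarity, or a tibble when `aggregate = FALSE`.
#' @examples
#' gliding_box_lacunarity(matrix(TRUE, 16, 16))  # exactly 1
#' @export
gliding_box_lacunarity <- function(img, box_sizes = c(2, 4, 8, 16, 32),
                                   aggregate = TRUE) {
  if (is.numeric(img)) img <- img != 0
  stopifnot(is.logical(img), is.matrix(img))
  if (!any(img)) abort("Lacunarity of an all-empty image is undefined.")
  box_sizes <- box_sizes[box_sizes <= min(dim(img))]
  if (length(box_sizes) == 0) abort("No box size fits within the image.")
  # summed-area table for O(1) box sums
  sat <- apply(apply(img, 2, cumsum), 1, cumsum)
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  box_sum <- function(r) {
    nr <- nrow(img); nc <- ncol(img)
    i <- 1:(nr - r + 1); j <- 1:(nc - r + 1)
    sat[i + r, j + r, drop = FALSE] - sat[i, j + r, drop = FALSE] -
      sat[i + r, j, drop = FALSE] + sat[i, j, drop = FALSE]
  }
  lam <- purrr::map_dbl(box_sizes, function(r) {
    m <- as.vector(box_sum(r))
    mean(m^2) / mean(m)^2
  })
  if (aggregate) mean(lam) else tibble::tibble(r = box_sizes, lambda = lam)
}

#' Derived gluten-network ratios
#'
#' The three ratio descriptors of a skeletonized protein network: branching
#' rate (junctions per unit protein area), endpoint rate (endpoints per unit
#' area) and average protein width (area over total skeleton length).
#'
#' @param protein_area_um2 Total protein area, square micrometres (> 0).
#' @param n_junctions,n_endpoints Junction and endpoint counts (>= 0).
#' @param total_length_um Total skeleton length, micrometres (> 0).
#' @return A one-row tibble: `branching_rate` (junctions/um^2),
#'   `endpoint_rate` (endpoints/um^2), `protein_width_um`.
#' @examples
#' derived_ratios(91909, 480, 418, 14200)
#' @export
derived_ratios <- function(protein_area_um2, n_junctions, n_endpoints,
                           total_length_um) {
  if (any(protein_area_um2 <= 0)) abort("`protein_area_um2` must be > 0.")
  if (any(total_length_um <= 0)) abort("`total_length_um` must be > 0.")
  stopifnot(all(n_junctions >= 0), all(n_endpoints >= 0))
  tibble::tibble(
    branching_rate = n_junctions / protein_area_um2,
    endpoint_rate = n_endpoints / protein_area_um2,
    protein_width_um = protein_area_um2 / total_length_um
  )
}

#' Full metric set of a binary protein-network image
#'
#' Skeletonizes the mask, decomposes the skeleton into junctions, endpoints
#' and branches, and assembles areas, lengths, gliding-box lacunarity and
#' the derived ratio descriptors.
#'
#' @param img Logical (or 0/1) matrix, `TRUE` = protein.
#' @param pixel_size Micrometres per pixel (default 1).
#' @param box_sizes Lacunarity box sizes (see [gliding_box_lacunarity()]).
#' @return A one-row tibble with `protein_area_um2`, `n_junctions`,
#'   `n_endpoints`, `n_branches`, `total_length_um`, `avg_length_um`,
#'   `lacunarity`, `branching_rate`, `endpoint_rate`, `protein_width_um`.
#' @export
network_metrics <- function(img, pixel_size = 1,
                            box_sizes = c(2, 4, 8, 16, 32)) {
  if (is.numeric(img)) img <- img != 0
  stopifnot(is.logical(img), is.matrix(img), pixel_size > 0)
  if (!any(img)) abort("Empty mask: no protein area.")
  area <- sum(img) * pixel_size^2
  skel <- skeletonize_image(img)
  g <- skeleton_graph(skel, pixel_size)
  lac <- gliding_box_lacunarity(img, box_sizes)
  ratios <- if (g$total_length_um > 0) {
    derived_ratios(area, g$n_junctions, g$n_endpoints, g$total_length_um)
  } else {
    tibble::tibble(branching_rate = g$n_junctions / area,
                   endpoint_rate = g$n_endpoints / area,
                   protein_width_um = NA_real_)
  }
  dplyr::bind_cols(
    tibble::tibble(
      protein_area_um2 = area,
      n_junctions = g$n_junctions,
      n_endpoints = g$n_endpoints,
      n_branches = nrow(g$branches),
      total_length_um = g$total_length_um,
      avg_length_um = g$avg_length_um,
      lacunarity = lac
    ),
    ratios
  )
}

#' Read a network image file as a binary mask
#'
#' Reads a single-channel PNG or TIFF (first channel of multi-channel input)
#' and binarizes grayscale content by Otsu's threshold unless a fixed
#' `threshold` in `[0, 1]` is given. Requires the `png` or `tiff` package.
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @param threshold `"otsu"` (default) or a numeric cutoff; pixels strictly
#'   above the cutoff are foreground.
#' @return Logical matrix.
#' @export
read_network_image <- function(path, threshold = "otsu") {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) abort("Package 'png' is required.")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) abort("Package 'tiff' is required.")
    tiff::readTIFF(path)
  } else {
    abort(sprintf("Unsupported image extension '%s'.", ext))
  }
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(arr)
  arr > threshold
}

# Otsu's method on a 256-bin histogram of values in [0, 1]
otsu_threshold <- function(x) {
  h <- tabulate(pmin(pmax(floor(x * 255), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 1) / 255
}

#' Plot a network mask with its skeleton overlay
#'
#' @param img Logical matrix (the mask).
#' @param skel Optional skeleton matrix; computed if missing.
#' @return A ggplot object.
#' @export
plot_network <- function(img, skel = NULL) {
  if (is.numeric(img)) img <- img != 0
  skel <- skel %||% skeletonize_image(img)
  to_df <- function(m, what) {
    idx <- which(m, arr.ind = TRUE)
    tibble::tibble(row = idx[, 1], col = idx[, 2], what = what)
  }
  df <- dplyr::bind_rows(to_df(img, "mask"), to_df(skel, "skeleton"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   colour = .data$what)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c(mask = "grey80", skeleton = "black")) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL)
}
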