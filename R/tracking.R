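#' Track segmented cells across frames and reconstruct genealogy
#'
#' Links regions between consecutive frames by maximal mask overlap (ties
#' broken by smaller centroid displacement, deterministically). A
#' one-to-two overlap event is a *provisional* division: segmentation tends
#' to split the two halves of a constricting cell before scission, so the
#' event is only confirmed once the two candidate daughters are genuinely
#' apart — their long axes deviate by more than 15 degrees or the gap
#' between them exceeds 1 pixel — for 2 consecutive frames. Until
#' confirmation the two regions are analysed as one cell (their pixel
#' union); if they re-merge the split is discarded as noise. On
#' confirmation the division is dated to the first frame of the separated
#' streak, and each daughter's new pole is the end adjacent to its sibling
#' at that frame. Pole polarity is defined only for cells whose birth was
#' observed and never changes within a cell's life. A cell is a *complete
#' cycle* when it was followed from its observed birth to its own confirmed
#' division.
#'
#' @param frames A list of segmentation tables from [segment_cells()], one
#'   per frame, in temporal order (>= 2 frames).
#' @param frame_index Integer frame indices (default `0:(n-1)`).
#' @param frame_interval Minutes between frames (for the `time` column).
#' @return An object of class `lineage_set`: a list with
#'   \describe{
#'     \item{cells}{tibble: `track_id`, `mother_id`, `birth_frame`,
#'       `division_frame` (frame at which the daughters first stand apart;
#'       `NA` if never), `divided`, `birth_observed`, `complete`,
#'       `old_pole_low` (`TRUE` when the old pole sits at the low end of
#'       the principal axis), `polarity_known`, `n_frames`.}
#'     \item{observations}{tibble: `track_id`, `frame`, `time`, `merged`
#'       (was this a provisionally split pair analysed as one?), and a
#'       list-column `region` with a one-row region table.}
#'   }
#' @export
track_and_genealogy <- function(frames, frame_index = NULL,
                                frame_interval = 1) {
  if (length(frames) < 2) {
    stop("tracking needs at least 2 frames.", call. = FALSE)
  }
  frame_index <- frame_index %||% (seq_along(frames) - 1L)
  pixel_size <- attr(frames[[1]], "pixel_size") %||% 1
  dim_img <- attr(frames[[1]], "dim_img")

  st <- new.env(parent = emptyenv())
  st$n <- 0L
  st$tracks <- list()   # track_id -> record
  st$obs <- list()

  new_track <- function(mother, birth_i, birth_observed,
                        old_pole_low = NA, polarity_known = FALSE) {
    st$n <- st$n + 1L
    id <- paste0("T", st$n)
    st$tracks[[id]] <- list(
      track_id = id, mother_id = mother, birth_i = birth_i,
      birth_observed = birth_observed, old_pole_low = old_pole_low,
      polarity_known = polarity_known, division_i = NA_integer_,
      divided = FALSE, last_i = birth_i)
    id
  }
  add_obs <- function(track_id, i, region_row, merged = FALSE) {
    st$obs[[length(st$obs) + 1L]] <- tibble::tibble(
      track_id = track_id, frame = frame_index[i],
      time = frame_index[i] * frame_interval, merged = merged,
      region = list(region_row))
    st$tracks[[track_id]]$last_i <- i
  }

  # current assignment: one entry per live track
  #   list(tid, sides = list of region-row tibbles (1 normally, 2 pending),
  #        pending = NULL | list(streak, history = list of
  #                              list(i, a, b, sep)))
  cur <- list()
  seg1 <- frames[[1]]
  for (r in seq_len(nrow(seg1))) {
    tid <- new_track(NA_character_, 1L, FALSE)
    add_obs(tid, 1L, seg1[r, , drop = FALSE])
    cur[[tid]] <- list(tid = tid, sides = list(seg1[r, , drop = FALSE]),
                       pending = NULL)
  }

  flush_pending_as_mother <- function(tr) {
    # record the whole pending history as merged mother observations
    for (h in tr$pending$history) {
      add_obs(tr$tid, h$i, merge_region_rows(h$a, h$b, dim_img, pixel_size),
              merged = TRUE)
    }
  }

  confirm_division <- function(tr, div_k) {
    # frames before div_k in history stay with the mother (merged);
    # from div_k on, sides a and b become daughters
    hist <- tr$pending$history
    for (h in hist[seq_len(div_k - 1L)]) {
      add_obs(tr$tid, h$i, merge_region_rows(h$a, h$b, dim_img, pixel_size),
              merged = TRUE)
    }
    div_i <- hist[[div_k]]$i
    st$tracks[[tr$tid]]$division_i <- div_i
    st$tracks[[tr$tid]]$divided <- TRUE
    pol <- daughter_polarity(hist[[div_k]]$a, hist[[div_k]]$b)
    ta <- new_track(tr$tid, div_i, TRUE, pol$a, TRUE)
    tb <- new_track(tr$tid, div_i, TRUE, pol$b, TRUE)
    for (h in hist[div_k:length(hist)]) {
      add_obs(ta, h$i, h$a)
      add_obs(tb, h$i, h$b)
    }
    list(list(tid = ta, sides = list(hist[[length(hist)]]$a),
              pending = NULL),
         list(tid = tb, sides = list(hist[[length(hist)]]$b),
              pending = NULL))
  }

  for (i in 2L:length(frames)) {
    seg <- frames[[i]]
    # map: region_id of frame i-1 -> (track slot index, side index)
    owner <- list()
    for (s in seq_along(cur)) {
      for (sd in seq_along(cur[[s]]$sides)) {
        for (rid in cur[[s]]$sides[[sd]]$region_id) {
          owner[[as.character(rid)]] <- c(s, sd)
        }
      }
    }
    lab_prev <- label_from_sides(cur, dim_img)
    lab <- region_label_matrix(seg)
    mother_of <- link_regions(register_labels(lab_prev, lab), lab, cur,
                              frames[[i - 1]], seg)

    # group children by owning track
    child_track <- rep(NA_integer_, nrow(seg))
    child_side <- rep(NA_integer_, nrow(seg))
    for (j in seq_len(nrow(seg))) {
      mo <- mother_of[j]
      if (!is.na(mo) && !is.null(owner[[as.character(mo)]])) {
        child_track[j] <- owner[[as.character(mo)]][1]
        child_side[j] <- owner[[as.character(mo)]][2]
      }
    }

    nxt <- list()
    for (s in seq_along(cur)) {
      tr <- cur[[s]]
      kids <- which(!is.na(child_track) & child_track == s)
      if (length(kids) > 2) {
        # fold extras into the nearest of the two largest
        ordk <- kids[order(-seg$area_px[kids])]
        pair <- ordk[1:2]
        for (e in ordk[-(1:2)]) {
          k <- pair[which.min((seg$cx[pair] - seg$cx[e])^2 +
                                (seg$cy[pair] - seg$cy[e])^2)]
          seg[k, ] <- merge_region_rows(seg[k, , drop = FALSE],
                                        seg[e, , drop = FALSE],
                                        dim_img, pixel_size,
                                        keep_id = seg$region_id[k])
          seg$pixels[[e]] <- integer(0)
          seg$area_px[e] <- 0L
        }
        kids <- pair
      }
      if (length(kids) == 0) {
        # lost from the field: close the track
        if (!is.null(tr$pending)) flush_pending_as_mother(tr)
        next
      }
      if (length(kids) == 1) {
        j <- kids
        if (!is.null(tr$pending)) flush_pending_as_mother(tr)  # noise split
        add_obs(tr$tid, i, seg[j, , drop = FALSE])
        nxt[[length(nxt) + 1L]] <- list(
          tid = tr$tid, sides = list(seg[j, , drop = FALSE]),
          pending = NULL)
        next
      }
      # two children
      a <- seg[kids[1], , drop = FALSE]
      b <- seg[kids[2], , drop = FALSE]
      same_side <- !is.na(child_side[kids[1]]) &&
        child_side[kids[1]] == child_side[kids[2]] &&
        length(tr$sides) == 2
      if (!is.null(tr$pending) && !same_side) {
        # keep side identity stable: side 1 -> a
        if (child_side[kids[1]] == 2) { tmp <- a; a <- b; b <- tmp }
        p <- tr$pending
      } else {
        if (!is.null(tr$pending)) flush_pending_as_mother(tr)
        p <- list(streak = 0L, history = list())
      }
      sep_now <- pair_separated(a, b, dim_img)
      p$streak <- if (sep_now) p$streak + 1L else 0L
      p$history <- c(p$history, list(list(i = i, a = a, b = b,
                                          sep = sep_now)))
      if (p$streak >= 2L) {
        tr$pending <- p
        daughters <- confirm_division(tr, length(p$history) - 1L)
        nxt <- c(nxt, daughters)
      } else {
        nxt[[length(nxt) + 1L]] <- list(tid = tr$tid, sides = list(a, b),
                                        pending = p)
      }
    }

    # unclaimed regions: cells entering the field
    claimed <- unlist(lapply(nxt, function(t)
      lapply(t$sides, function(x) x$region_id)))
    for (j in seq_len(nrow(seg))) {
      if (seg$area_px[j] > 0 && !(seg$region_id[j] %in% claimed) &&
          is.na(child_track[j])) {
        tid <- new_track(NA_character_, i, FALSE)
        add_obs(tid, i, seg[j, , drop = FALSE])
        nxt[[length(nxt) + 1L]] <- list(
          tid = tid, sides = list(seg[j, , drop = FALSE]), pending = NULL)
      }
    }
    cur <- nxt
  }
  # close out surviving pendings
  for (tr in cur) if (!is.null(tr$pending)) flush_pending_as_mother(tr)

  cells <- dplyr::bind_rows(lapply(st$tracks, function(t) {
    tibble::tibble(
      track_id = t$track_id, mother_id = t$mother_id,
      birth_frame = frame_index[t$birth_i],
      division_frame = if (is.na(t$division_i)) NA_integer_ else
        frame_index[t$division_i],
      divided = t$divided, birth_observed = t$birth_observed,
      complete = t$birth_observed && t$divided,
      old_pole_low = t$old_pole_low, polarity_known = t$polarity_known)
  }))
  observations <- dplyr::bind_rows(st$obs) |>
    dplyr::arrange(.data$track_id, .data$frame)
  n_frames <- dplyr::count(observations, .data$track_id, name = "n_frames")
  cells <- dplyr::left_join(cells, n_frames, by = "track_id") |>
    dplyr::mutate(n_frames = dplyr::coalesce(.data$n_frames, 0L))

  structure(list(cells = cells, observations = observations,
                 frame_index = frame_index,
                 frame_interval = frame_interval,
                 pixel_size = pixel_size, dim_img = dim_img),
            class = "lineage_set")
}

#' @export
print.lineage_set <- function(x, ...) {
  cat("<lineage_set>", nrow(x$cells), "tracks over",
      length(x$frame_index), "frames;",
      sum(x$cells$complete), "complete cycle(s)\n")
  invisible(x)
}

# label matrix of the previous frame as the tracker sees it (per side)
label_from_sides <- function(cur, dim_img) {
  lab <- matrix(0L, dim_img[1], dim_img[2])
  for (tr in cur) {
    for (sd in tr$sides) {
      for (r in seq_len(nrow(sd))) lab[sd$pixels[[r]]] <- sd$region_id[r]
    }
  }
  lab
}

# Growth registration: cells stacked in a colony row drift in proportion
# to their position as everything elongates, which erodes frame-to-frame
# mask overlap at the row ends. Before overlap linking, the previous
# frame's labels are rescaled along x, per horizontal band of cells, so
# that the band's occupied extent matches the current frame's.
register_labels <- function(lab_prev, lab_cur) {
  idx_p <- which(lab_prev > 0)
  idx_c <- which(lab_cur > 0)
  if (!length(idx_p) || !length(idx_c)) return(lab_prev)
  ny <- nrow(lab_prev)
  yp <- (idx_p - 1) %% ny
  xp <- (idx_p - 1) %/% ny
  yc <- (idx_c - 1) %% ny
  xc <- (idx_c - 1) %/% ny
  # horizontal bands: rows occupied in either frame, split at gaps > 5 px
  rows <- sort(unique(c(yp, yc)))
  splits <- which(diff(rows) > 5)
  starts <- c(1, splits + 1)
  ends <- c(splits, length(rows))
  out <- matrix(0L, nrow(lab_prev), ncol(lab_prev))
  for (b in seq_along(starts)) {
    rlo <- rows[starts[b]]; rhi <- rows[ends[b]]
    inp <- yp >= rlo & yp <= rhi
    inc <- yc >= rlo & yc <= rhi
    if (!any(inp)) next
    p_rng <- range(xp[inp]); c_rng <- range(xc[inc])
    scale <- if (any(inc) && diff(p_rng) > 0)
      diff(c_rng) / diff(p_rng) else 1
    newx <- if (any(inc))
      pmin(pmax(round(c_rng[1] + (xp[inp] - p_rng[1]) * scale), 0),
           ncol(lab_prev) - 1) else xp[inp]
    tgt <- yp[inp] + 1 + newx * ny
    out[tgt] <- lab_prev[idx_p[inp]]
  }
  # fill single-column gaps introduced by the rescaling
  for (j in 2:(ncol(out) - 1)) {
    z <- out[, j] == 0 & out[, j - 1] != 0 & out[, j + 1] == out[, j - 1]
    if (any(z)) out[z, j] <- out[z, j - 1]
  }
  out
}

# for each region of `seg`, the region_id in the previous frame with the
# largest mask overlap (ties by centroid distance); NA if none
link_regions <- function(lab_prev, lab, cur, seg_prev, seg) {
  mother_of <- rep(NA_integer_, nrow(seg))
  both <- lab_prev > 0 & lab > 0
  if (!any(both)) return(mother_of)
  ov <- table(prev = lab_prev[both], cur = lab[both])
  prev_ids <- as.integer(rownames(ov))
  cur_ids <- as.integer(colnames(ov))
  for (j in seq_len(nrow(seg))) {
    cj <- match(seg$region_id[j], cur_ids)
    if (is.na(cj)) next
    col <- ov[, cj]
    mx <- max(col)
    if (mx == 0) next
    best <- which(col == mx)
    if (length(best) > 1) {
      cand <- prev_ids[best]
      dd <- vapply(cand, function(pid) {
        k <- match(pid, seg_prev$region_id)
        if (is.na(k)) return(Inf)
        (seg_prev$cx[k] - seg$cx[j])^2 + (seg_prev$cy[k] - seg$cy[j])^2
      }, numeric(1))
      best <- best[which.min(dd)]
    }
    mother_of[j] <- prev_ids[best]
  }
  mother_of
}

# are two candidate daughter regions truly separate? (axis deviation
# > 15 degrees, or an axial gap of more than 1 pixel between the masks)
pair_separated <- function(a, b, dim_img, angle_deg = 15, gap_px = 1) {
  dth <- abs(a$angle - b$angle) %% pi
  dth <- min(dth, pi - dth) * 180 / pi
  if (dth > angle_deg) return(TRUE)
  # project both masks on the inter-centroid axis
  v <- c(b$cx - a$cx, b$cy - a$cy)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(FALSE)
  v <- v / nv
  proj <- function(r) {
    idx <- r$pixels[[1]]
    y <- (idx - 1) %% dim_img[1]; x <- (idx - 1) %/% dim_img[1]
    x * v[1] + y * v[2]
  }
  qa <- proj(a); qb <- proj(b)
  gap <- max(min(qb) - max(qa), min(qa) - max(qb))
  gap > gap_px
}

# union two region rows into one (recomputed geometry)
merge_region_rows <- function(a, b, dim_img, pixel_size, keep_id = NULL) {
  idx <- sort(unique(c(a$pixels[[1]], b$pixels[[1]])))
  out <- region_props(idx, dim_img, pixel_size,
                      keep_id %||% a$region_id[1])
  attr(out, "dim_img") <- dim_img
  attr(out, "pixel_size") <- pixel_size
  out
}

# which end of each daughter faces the sibling: that end is the new pole
daughter_polarity <- function(a, b) {
  ends <- function(r) {
    u <- c(cos(r$angle), sin(r$angle))
    list(low = c(r$cx, r$cy) + r$proj_min * u,
         high = c(r$cx, r$cy) + r$proj_max * u)
  }
  d2 <- function(p, q) sum((p - q)^2)
  ea <- ends(a); eb <- ends(b)
  cb <- c(b$cx, b$cy); ca <- c(a$cx, a$cy)
  # new pole of a = end nearer b  =>  old pole at the other end
  a_new_high <- d2(ea$high, cb) < d2(ea$low, cb)
  b_new_high <- d2(eb$high, ca) < d2(eb$low, ca)
  list(a = a_new_high,   # old_pole_low = TRUE when new pole is high end
       b = b_new_high)
}
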