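# Track building and RNA/translation-site linking.

#' Link per-frame spots into tracks
#'
#' Greedy nearest-neighbour assignment per frame transition with cost equal to
#' squared displacement, rejecting moves larger than `max_disp` px per frame
#' (scaled across closed gaps), and gap closing up to `max_gap` missing
#' frames.  When two tracks claim the same spot the nearer track wins and both
#' involved tracks are flagged `merged`; when an unassigned spot appears
#' within `max_disp` of a track's previous position the track is flagged
#' `split` and the spot seeds a new (also `split`-flagged) track.
#'
#' @param spots Data frame with columns `frame` (0-based), `x`, `y` and
#'   optionally `amplitude`.
#' @param max_disp Maximum displacement, px per frame.
#' @param max_gap Maximum number of missing frames closed within a track.
#' @return A list of class `track_set`: `points` (spot rows with `track_id`)
#'   and `tracks` (per track: `track_id`, `first_frame`, `last_frame`,
#'   `n_points`, `length_frames`, `merged`, `split`).
#' @export
link_spots <- function(spots, max_disp = 5, max_gap = 2) {
  pts_cols <- intersect(c("frame", "x", "y", "amplitude"), names(spots))
  if (!nrow(spots)) {
    return(structure(list(
      points = cbind(data.frame(track_id = integer(0)), spots[pts_cols]),
      tracks = data.frame(track_id = integer(0), first_frame = integer(0),
                          last_frame = integer(0), n_points = integer(0),
                          length_frames = integer(0), merged = logical(0),
                          split = logical(0))), class = "track_set"))
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  next_id <- 1L
  active <- list()   # each: id, last_frame, x, y, rows, merged, split
  done <- list()
  row_track <- integer(nrow(spots))
  spot_rows <- split(seq_len(nrow(spots)), spots$frame)

  for (f in frames) {
    rows_f <- spot_rows[[as.character(f)]]
    sx <- spots$x[rows_f]; sy <- spots$y[rows_f]
    n_s <- length(rows_f)
    assigned_spot <- rep(FALSE, n_s)
    extended <- rep(FALSE, length(active))
    prev_xy <- NULL

    if (length(active)) {
      # retire tracks whose gap can no longer be closed
      gaps <- vapply(active, function(a) as.numeric(f - a$last_frame - 1L), numeric(1))
      retire <- gaps > max_gap
      done <- c(done, active[retire])
      active <- active[!retire]
      extended <- rep(FALSE, length(active))
    }
    if (length(active) && n_s) {
      steps <- vapply(active, function(a) as.numeric(f - a$last_frame), numeric(1))
      ax <- vapply(active, function(a) a$x, numeric(1))
      ay <- vapply(active, function(a) a$y, numeric(1))
      prev_xy <- cbind(ax, ay)
      d <- sqrt(outer(ax, sx, "-")^2 + outer(ay, sy, "-")^2)
      lim <- max_disp * steps
      cand <- which(d <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        track_used <- rep(FALSE, length(active))
        lost_cands <- integer(0)
        winner_of_spot <- rep(NA_integer_, n_s)
        for (k in seq_len(nrow(cand))) {
          ti <- cand[k, 1]; si <- cand[k, 2]
          if (!track_used[ti] && !assigned_spot[si]) {
            track_used[ti] <- TRUE
            assigned_spot[si] <- TRUE
            extended[ti] <- TRUE
            winner_of_spot[si] <- ti
            r <- rows_f[si]
            active[[ti]]$rows <- c(active[[ti]]$rows, r)
            active[[ti]]$last_frame <- f
            active[[ti]]$x <- sx[si]; active[[ti]]$y <- sy[si]
            row_track[r] <- active[[ti]]$id
          } else if (!track_used[ti] && assigned_spot[si]) {
            # a second track wanted an already-claimed spot: merge collision
            lost_cands <- c(lost_cands, k)
          }
        }
        for (k in lost_cands) {
          ti <- cand[k, 1]; si <- cand[k, 2]
          if (!track_used[ti]) {     # the loser ended here
            active[[ti]]$merged <- TRUE
            wi <- winner_of_spot[si]
            if (!is.na(wi)) active[[wi]]$merged <- TRUE
          }
        }
      }
    }
    # splits: unassigned spot near the previous position of an extended track
    if (n_s && !is.null(prev_xy)) {
      for (si in which(!assigned_spot)) {
        d2 <- (prev_xy[, 1] - sx[si])^2 + (prev_xy[, 2] - sy[si])^2
        near <- which(extended & d2 <= max_disp^2)
        if (length(near)) {
          active[[near[1]]]$split <- TRUE
          r <- rows_f[si]
          active[[length(active) + 1L]] <- list(
            id = next_id, last_frame = f, x = sx[si], y = sy[si],
            rows = r, merged = FALSE, split = TRUE)
          row_track[r] <- next_id
          next_id <- next_id + 1L
          assigned_spot[si] <- TRUE
          extended <- c(extended, TRUE)
        }
      }
    }
    # remaining spots start fresh tracks
    for (si in which(!assigned_spot)) {
      r <- rows_f[si]
      active[[length(active) + 1L]] <- list(
        id = next_id, last_frame = f, x = sx[si], y = sy[si],
        rows = r, merged = FALSE, split = FALSE)
      row_track[r] <- next_id
      next_id <- next_id + 1L
      extended <- c(extended, TRUE)
    }
  }
  done <- c(done, active)

  points <- cbind(data.frame(track_id = row_track), spots[pts_cols])
  points <- points[order(points$track_id, points$frame), , drop = FALSE]
  rownames(points) <- NULL
  tracks <- do.call(rbind, lapply(done, function(a) {
    fr <- spots$frame[a$rows]
    data.frame(track_id = a$id, first_frame = min(fr), last_frame = max(fr),
               n_points = length(a$rows),
               length_frames = max(fr) - min(fr) + 1L,
               merged = isTRUE(a$merged), split = isTRUE(a$split))
  }))
  tracks <- tracks[order(tracks$track_id), , drop = FALSE]
  rownames(tracks) <- NULL
  structure(list(points = points, tracks = tracks), class = "track_set")
}

#' Filter tracks by length and merge/split flags
#'
#' Keeps tracks strictly longer than `min_len` frames (length counts frames
#' spanned, including closed gaps, so the default keeps length >= 6) and, when
#' `drop_merge_split`, without merge or split collisions.  Exclusion tallies
#' are attached as the `"exclusions"` attribute.
#'
#' @param track_set A [link_spots()] result.
#' @param min_len Tracks must be longer than this many frames.
#' @param drop_merge_split Drop tracks with merge/split flags.
#' @return A filtered `track_set`.
#' @export
filter_tracks <- function(track_set, min_len = 5L, drop_merge_split = TRUE) {
  tr <- track_set$tracks
  short <- tr$length_frames <= min_len
  ms <- if (drop_merge_split) (tr$merged | tr$split) else rep(FALSE, nrow(tr))
  keep <- !short & !ms
  out <- structure(list(
    points = track_set$points[track_set$points$track_id %in% tr$track_id[keep], ,
                              drop = FALSE],
    tracks = tr[keep, , drop = FALSE]), class = "track_set")
  attr(out, "exclusions") <- c(short_track = sum(short),
                               merge_split = sum(ms & !short))
  out
}

#' Link RNA tracks to translation-site (protein) tracks
#'
#' Pairs each protein track with the RNA track whose time-averaged
#' inter-centroid distance over co-existing frames is minimal and at most
#' `max_dist` px, requiring co-existence of at least `min_overlap` frames.
#' Each protein track links to at most one RNA, and each RNA keeps at most one
#' protein track per channel (largest overlap, then smallest distance).  Ties
#' at identical mean distance break deterministically towards the lower RNA
#' track id.
#'
#' @param rna A `track_set` of RNA-channel tracks (filtered).
#' @param protein A named list of `track_set`s, one per protein channel
#'   (e.g. `list(ch1 = ..., ch2 = ...)`), or a single `track_set` (taken as
#'   channel `ch1`).
#' @param max_dist Maximum time-averaged distance, px.
#' @param min_overlap Minimum number of co-existing frames.
#' @return List of class `linked_traces`: `links` (per RNA: `rna_track`,
#'   `ch1_track`, `ch2_track`, `overlap_ch1`, `overlap_ch2`), `traces`
#'   (per-link intensity trace on the RNA track's frames, protein amplitude 0
#'   where the protein track is absent), and `orphans` (protein tracks left
#'   unlinked, with channel).
#' @export
link_rna_protein <- function(rna, protein, max_dist = 3, min_overlap = 5L) {
  if (inherits(protein, "track_set")) protein <- list(ch1 = protein)
  rna_pts <- split(rna$points, rna$points$track_id)
  rna_ids <- sort(rna$tracks$track_id)

  assign_channel <- function(ts) {
    pts <- split(ts$points, ts$points$track_id)
    out <- lapply(names(pts), function(pid) {
      pp <- pts[[pid]]
      best <- NULL
      for (rid in rna_ids) {
        rp <- rna_pts[[as.character(rid)]]
        co <- intersect(pp$frame, rp$frame)
        if (length(co) < min_overlap) next
        di <- mean(sqrt((pp$x[match(co, pp$frame)] - rp$x[match(co, rp$frame)])^2 +
                        (pp$y[match(co, pp$frame)] - rp$y[match(co, rp$frame)])^2))
        if (di <= max_dist &&
            (is.null(best) || di < best$dist - 1e-12)) {
          best <- list(rna = rid, dist = di, overlap = length(co))
        }
      }
      data.frame(protein_track = as.integer(pid),
                 rna_track = if (is.null(best)) NA_integer_ else best$rna,
                 dist = if (is.null(best)) NA_real_ else best$dist,
                 overlap = if (is.null(best)) 0L else best$overlap)
    })
    do.call(rbind, out)
  }

  links <- data.frame(rna_track = rna_ids,
                      ch1_track = NA_integer_, ch2_track = NA_integer_,
                      overlap_ch1 = 0L, overlap_ch2 = 0L)
  orphans <- list()
  for (ch in names(protein)) {
    a <- assign_channel(protein[[ch]])
    if (is.null(a)) next
    linked <- a[!is.na(a$rna_track), , drop = FALSE]
    # one protein track per RNA per channel: largest overlap, then distance
    linked <- linked[order(linked$rna_track, -linked$overlap, linked$dist), ,
                     drop = FALSE]
    chosen <- linked[!duplicated(linked$rna_track), , drop = FALSE]
    dropped <- setdiff(a$protein_track, chosen$protein_track)
    if (length(dropped))
      orphans[[ch]] <- data.frame(channel = ch, protein_track = dropped)
    i <- match(chosen$rna_track, links$rna_track)
    links[[paste0(ch, "_track")]][i] <- chosen$protein_track
    links[[paste0("overlap_", ch)]][i] <- chosen$overlap
  }
  orphans <- if (length(orphans)) do.call(rbind, orphans) else
    data.frame(channel = character(0), protein_track = integer(0))

  traces <- lapply(seq_len(nrow(links)), function(i) {
    rid <- links$rna_track[i]
    rp <- rna_pts[[as.character(rid)]]
    tr <- data.frame(rna_track = rid, frame = rp$frame,
                     rna_signal = if ("amplitude" %in% names(rp)) rp$amplitude else NA_real_)
    for (ch in names(protein)) {
      pid <- links[[paste0(ch, "_track")]][i]
      sig <- rep(0, nrow(rp))
      if (!is.na(pid)) {
        pp <- protein[[ch]]$points
        pp <- pp[pp$track_id == pid, , drop = FALSE]
        m <- match(rp$frame, pp$frame)
        sig[!is.na(m)] <- if ("amplitude" %in% names(pp))
          pp$amplitude[m[!is.na(m)]] else 1
      }
      tr[[paste0(ch, "_signal")]] <- sig
    }
    tr
  })
  traces <- do.call(rbind, traces)
  structure(list(links = links, traces = traces, orphans = orphans,
                 max_dist = max_dist, min_overlap = min_overlap),
            class = "linked_traces")
}
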