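## pixel overlap between two masks (linear indices into the same raster)
.mask_overlap <- function(a, b) length(intersect(a$pixels, b$pixels))

#' Link cell masks between two consecutive frames of one trench
#'
#' Overlap-maximizing assignment: each new-frame mask is matched to the
#' old-frame mask it overlaps most (ties broken by smaller centroid
#' displacement, then smaller label).  A new mask with no overlap is assigned
#' as a daughter of the nearest old mask if it lies within `proximity_um`
#' along the trench axis (a freshly divided cell abuts its sibling without
#' overlapping the parent's previous footprint); otherwise it is flagged
#' washed-in when it sits beyond the deepest known cell toward the open end,
#' or orphan otherwise.  Old masks end up with 0 (disappearance), 1
#' (continuation) or >=2 (division) successors.
#'
#' @param masks_t,masks_t1 lists of masks from [segment_cells()] for the same
#'   trench at consecutive scheduled frames (either may be empty).
#' @param pixels_per_micron raster scale.
#' @param proximity_um axial proximity fallback for division daughters (um).
#' @return list with `assign` (one row per new mask: `label`, `parent_label`,
#'   `relation` in continuation/daughter/washed_in/orphan) and `events` (one
#'   row per old mask: `label`, `n_children`, `event` in
#'   continuation/division/disappearance).
#' @export
link_frames <- function(masks_t, masks_t1, pixels_per_micron,
                        proximity_um = 4) {
  n0 <- length(masks_t)
  n1 <- length(masks_t1)
  lab0 <- vapply(masks_t, `[[`, numeric(1), "label")
  lab1 <- vapply(masks_t1, `[[`, numeric(1), "label")
  row0 <- vapply(masks_t, function(m) m$centroid_px[1], numeric(1))
  row1 <- vapply(masks_t1, function(m) m$centroid_px[1], numeric(1))

  parent <- rep(NA_real_, n1)
  relation <- rep(NA_character_, n1)
  if (n0 && n1) {
    ov <- outer(seq_len(n0), seq_len(n1),
                Vectorize(function(i, j) .mask_overlap(masks_t[[i]],
                                                       masks_t1[[j]])))
    for (j in order(row1)) {
      cand <- which(ov[, j] > 0)
      if (length(cand)) {
        best <- cand[order(-ov[cand, j], abs(row0[cand] - row1[j]),
                           lab0[cand])][1]
        parent[j] <- lab0[best]
      }
    }
    ## proximity fallback for unmatched masks (division daughters)
    for (j in which(is.na(parent))) {
      d <- abs(row0 - row1[j]) / pixels_per_micron
      if (min(d) <= proximity_um)
        parent[j] <- lab0[order(d, lab0)][1]
    }
  }
  matched <- !is.na(parent)
  if (any(!matched)) {
    deepest <- if (n0) max(row0) else -Inf
    relation[!matched] <- ifelse(row1[!matched] >= deepest,
                                 "washed_in", "orphan")
  }
  ## among a parent's children, the one nearest the closed end continues it
  for (p in unique(parent[matched])) {
    ch <- which(!is.na(parent) & parent == p)
    ch <- ch[order(row1[ch])]
    relation[ch] <- c("continuation", rep("daughter", length(ch) - 1))
  }
  n_children <- if (n0) vapply(lab0, function(l)
    sum(!is.na(parent) & parent == l), numeric(1)) else numeric(0)
  events <- data.frame(
    label = lab0, n_children = n_children,
    event = c("disappearance", "continuation", "division")[
      pmin(n_children, 2) + 1])
  list(assign = data.frame(label = lab1, parent_label = parent,
                           relation = relation),
       events = events)
}

#' Build lineages from per-frame masks of one trench
#'
#' Chains [link_frames()] assignments over the full imaging schedule into
#' lineage tracks, with division, disappearance and end-of-movie events.  A
#' track missing for a single frame is bridged (its mask is matched against
#' the frame after the gap); a track absent for two consecutive frames is
#' confirmed disappeared at the first missing frame.  Washed-in masks are
#' excluded from lineages but counted.
#'
#' @param masks_by_frame list (one element per scheduled frame) of mask lists
#'   from [segment_cells()], all from the same trench.
#' @param schedule frame times in hours, same length as `masks_by_frame`.
#' @param pixels_per_micron raster scale.
#' @param proximity_um see [link_frames()].
#' @return object of class `mm_lineages`: list with `tracks` (track_id,
#'   parent_track, founder, start_h), `frames` (track_id, frame_h, label,
#'   present, bridged), `events` (track_id, time_h, kind) and `washed_in`
#'   (frame_h, n).
#' @export
build_lineages <- function(masks_by_frame, schedule, pixels_per_micron,
                           proximity_um = 4) {
  stopifnot(length(masks_by_frame) == length(schedule))
  k <- length(schedule)

  tracks <- list()     # track_id -> list(parent, founder, start_h)
  track_mask <- list() # track_id -> last observed mask
  missing_since <- list() # track_id -> frame index first missing, or NULL
  frames_rows <- list()
  events_rows <- list()
  washed <- integer(k)
  owner <- list() # label -> track_id for the current frame
  next_id <- 1L

  new_track <- function(parent, founder, i, mask) {
    id <- next_id
    next_id <<- next_id + 1L
    tracks[[id]] <<- list(parent = parent, founder = founder,
                          start_h = schedule[i])
    track_mask[[id]] <<- mask
    frames_rows[[length(frames_rows) + 1]] <<-
      data.frame(track_id = id, frame_h = schedule[i], label = mask$label,
                 present = TRUE, bridged = FALSE)
    id
  }

  ## founders at t = 0, ordered from the closed end
  m0 <- masks_by_frame[[1]]
  for (m in m0[order(vapply(m0, function(m) m$centroid_px[1], numeric(1)))])
    owner[[as.character(m$label)]] <- new_track(NA, TRUE, 1, m)

  for (i in seq_len(k - 1)) {
    cur <- masks_by_frame[[i]]
    cur <- Filter(function(m) !is.null(owner[[as.character(m$label)]]), cur)
    nxt <- masks_by_frame[[i + 1]]
    lf <- link_frames(cur, nxt, pixels_per_micron, proximity_um)

    new_owner <- list()
    assigned <- rep(FALSE, length(nxt))
    lab_nxt <- vapply(nxt, `[[`, numeric(1), "label")

    for (r in seq_len(nrow(lf$assign))) {
      a <- lf$assign[r, ]
      j <- match(a$label, lab_nxt)
      if (!is.na(a$parent_label)) {
        ptrack <- owner[[as.character(a$parent_label)]]
        if (a$relation == "continuation") {
          new_owner[[as.character(a$label)]] <- ptrack
          track_mask[[ptrack]] <- nxt[[j]]
          missing_since[[as.character(ptrack)]] <- NULL
          frames_rows[[length(frames_rows) + 1]] <-
            data.frame(track_id = ptrack, frame_h = schedule[i + 1],
                       label = a$label, present = TRUE, bridged = FALSE)
        } else { # daughter
          id <- new_track(ptrack, FALSE, i + 1, nxt[[j]])
          new_owner[[as.character(a$label)]] <- id
        }
        assigned[j] <- TRUE
      }
    }
    ## one division event per dividing mother
    div <- lf$events[lf$events$event == "division", , drop = FALSE]
    for (l in div$label)
      events_rows[[length(events_rows) + 1]] <-
        data.frame(track_id = owner[[as.character(l)]],
                   time_h = schedule[i + 1], kind = "division")

    ## tracks whose mask at i had no successor go provisionally missing
    gone <- lf$events$label[lf$events$event == "disappearance"]
    for (l in gone)
      missing_since[[as.character(owner[[as.character(l)]])]] <- i + 1

    ## bridge tracks that went missing exactly one frame ago
    pending <- names(missing_since)[vapply(missing_since, function(x)
      isTRUE(x == i), logical(1))]
    for (tid_chr in pending) {
      tid <- as.integer(tid_chr)
      last <- track_mask[[tid]]
      cand <- which(!assigned)
      if (length(cand)) {
        ov <- vapply(cand, function(j) .mask_overlap(last, nxt[[j]]),
                     numeric(1))
        d <- vapply(cand, function(j)
          abs(last$centroid_px[1] - nxt[[j]]$centroid_px[1]) /
            pixels_per_micron, numeric(1))
        ok <- ov > 0 | d <= proximity_um
        if (any(ok)) {
          j <- cand[ok][order(-ov[ok], d[ok])][1]
          new_owner[[as.character(lab_nxt[j])]] <- tid
          track_mask[[tid]] <- nxt[[j]]
          missing_since[[tid_chr]] <- NULL
          assigned[j] <- TRUE
          frames_rows[[length(frames_rows) + 1]] <-
            data.frame(track_id = tid, frame_h = schedule[i],
                       label = NA, present = FALSE, bridged = TRUE)
          frames_rows[[length(frames_rows) + 1]] <-
            data.frame(track_id = tid, frame_h = schedule[i + 1],
                       label = lab_nxt[j], present = TRUE, bridged = FALSE)
          next
        }
      }
      ## absent two consecutive frames: confirmed disappearance
      events_rows[[length(events_rows) + 1]] <-
        data.frame(track_id = tid, time_h = schedule[i], kind = "disappearance")
      missing_since[[tid_chr]] <- NULL
      tracks[[tid]]$closed <- TRUE
    }

    ## leftover unmatched masks: washed-in excluded, orphans become tracks
    for (r in which(!is.na(lf$assign$relation) &
                      lf$assign$relation %in% c("washed_in", "orphan"))) {
      a <- lf$assign[r, ]
      j <- match(a$label, lab_nxt)
      if (assigned[j]) next # claimed by a bridged track
      if (a$relation == "washed_in") {
        washed[i + 1] <- washed[i + 1] + 1L
      } else {
        id <- new_track(NA, FALSE, i + 1, nxt[[j]])
        new_owner[[as.character(a$label)]] <- id
      }
      assigned[j] <- TRUE
    }
    owner <- new_owner
  }

  ## close out tracks at the end of the movie
  for (tid_chr in names(missing_since))
    events_rows[[length(events_rows) + 1]] <-
      data.frame(track_id = as.integer(tid_chr),
                 time_h = schedule[missing_since[[tid_chr]]],
                 kind = "disappearance")
  open_ids <- unlist(owner, use.names = FALSE)
  for (tid in unique(open_ids))
    events_rows[[length(events_rows) + 1]] <-
      data.frame(track_id = tid, time_h = schedule[k], kind = "end_of_movie")

  n_tracks <- next_id - 1L
  tracks_df <- data.frame(
    track_id = seq_len(n_tracks),
    parent_track = vapply(tracks, function(t)
      if (is.na(t$parent[1])) NA_integer_ else as.integer(t$parent),
      integer(1)),
    founder = vapply(tracks, function(t) isTRUE(t$founder), logical(1)),
    start_h = vapply(tracks, function(t) t$start_h, numeric(1)))
  frames_df <- if (length(frames_rows)) do.call(rbind, frames_rows) else
    data.frame(track_id = integer(), frame_h = numeric(), label = numeric(),
               present = logical(), bridged = logical())
  events_df <- if (length(events_rows)) do.call(rbind, events_rows) else
    data.frame(track_id = integer(), time_h = numeric(), kind = character())
  events_df <- events_df[order(events_df$track_id, events_df$time_h), ]
  rownames(events_df) <- NULL
  structure(list(tracks = tracks_df, frames = frames_df, events = events_df,
                 washed_in = data.frame(frame_h = schedule, n = washed)),
            class = "mm_lineages")
}

#' Subtree of tracks descending from (and including) a founder track
#'
#' @param lineages an `mm_lineages`.
#' @param track_id founder track id.
#' @return integer vector of track ids.
#' @export
lineage_subtree <- function(lineages, track_id) {
  out <- track_id
  repeat {
    kids <- lineages$tracks$track_id[
      !is.na(lineages$tracks$parent_track) &
        lineages$tracks$parent_track %in% out &
        !lineages$tracks$track_id %in% out]
    if (!length(kids)) break
    out <- c(out, kids)
  }
  sort(out)
}

#' @export
print.mm_lineages <- function(x, ...) {
  cat(sprintf("<mm_lineages> %d track(s), %d founder(s)\n",
              nrow(x$tracks), sum(x$tracks$founder)))
  if (nrow(x$events)) {
    tab <- table(x$events$kind)
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}
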