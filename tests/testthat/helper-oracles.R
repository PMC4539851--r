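# Brute-force oracles, written independently of the package internals:
# plain double loops over data-frame rows and the documented rules only.

oracle_status <- function(a, b, offset) {
  if (a$strand != b$strand) return("unique_without_overlap")
  ov <- min(a$stop, b$stop) - max(a$start, b$start) + 1
  if (ov < 1) return("unique_without_overlap")
  if (a$feature_type != b$feature_type) return("unique_with_overlap")
  if (a$start == b$start && a$stop == b$stop) return("identical")
  lmin <- min(a$stop - a$start + 1, b$stop - b$start + 1)
  if (abs(a$start - b$start) <= offset * lmin &&
      abs(a$stop - b$stop) <= offset * lmin) {
    if (a$feature_type == "CDS") {
      fr <- function(g) if (g$strand == "+") g$start %% 3 else g$stop %% 3
      if (isTRUE(a$is_discontiguous) || isTRUE(b$is_discontiguous))
        return("similar")
      if (fr(a) == fr(b)) return("similar")
      return("unique_with_overlap")
    }
    return("similar")
  }
  "unique_with_overlap"
}

# exhaustive all-pairs matcher with the documented preference order
oracle_match <- function(x, z, offset) {
  gx <- x$genes
  gz <- z$genes
  cand <- NULL
  for (i in seq_len(nrow(gx))) {
    for (j in seq_len(nrow(gz))) {
      if (gx$replicon_id[i] != gz$replicon_id[j]) next
      st <- oracle_status(gx[i, ], gz[j, ], offset)
      if (st == "unique_without_overlap") next
      cand <- rbind(cand, data.frame(
        i = i, j = j, status = st,
        dev = abs(gx$start[i] - gz$start[j]) + abs(gx$stop[i] - gz$stop[j]),
        shared = min(gx$stop[i], gz$stop[j]) - max(gx$start[i], gz$start[j]) + 1,
        stringsAsFactors = FALSE))
    }
  }
  x_status <- setNames(rep("unique_without_overlap", nrow(gx)), gx$uid)
  z_status <- setNames(rep("unique_without_overlap", nrow(gz)), gz$uid)
  pair_map <- character(0)   # uid_x -> uid_z for identical/similar pairs
  if (!is.null(cand)) {
    rank <- match(cand$status,
                  c("identical", "similar", "unique_with_overlap"))
    ord <- order(rank, cand$dev, -cand$shared, gz$start[cand$j],
                 gx$start[cand$i], gz$uid[cand$j], gx$uid[cand$i])
    cand <- cand[ord, ]
    x_used <- rep(FALSE, nrow(gx))
    z_used <- rep(FALSE, nrow(gz))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!x_used[i] && !z_used[j]) {
        x_used[i] <- TRUE
        z_used[j] <- TRUE
        x_status[i] <- cand$status[k]
        z_status[j] <- cand$status[k]
        if (cand$status[k] %in% c("identical", "similar"))
          pair_map[gx$uid[i]] <- gz$uid[j]
      }
    }
  }
  list(x_status = x_status, z_status = z_status, pair_map = pair_map)
}

# all-pairs internal overlap scan
oracle_overlaps <- function(ann, offset) {
  g <- ann$genes
  out <- NULL
  n <- nrow(g)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (g$replicon_id[i] != g$replicon_id[j]) next
        if (g$strand[i] != g$strand[j]) next
        ov <- min(g$stop[i], g$stop[j]) - max(g$start[i], g$start[j]) + 1
        if (ov < 1) next
        lmin <- min(g$stop[i] - g$start[i], g$stop[j] - g$start[j]) + 1
        sig <- abs(g$start[i] - g$start[j]) <= offset * lmin &&
               abs(g$stop[i] - g$stop[j]) <= offset * lmin
        out <- rbind(out, data.frame(
          uid1 = min(g$uid[i], g$uid[j]), uid2 = max(g$uid[i], g$uid[j]),
          kind = if (sig) "significant" else "short",
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    return(data.frame(uid1 = character(0), uid2 = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  out[order(out$uid1, out$uid2), ]
}

# greedy clique growth over oracle_match edges, seeded in input order
oracle_clusters <- function(annotations, offset) {
  n <- length(annotations)
  labels <- vapply(annotations, function(a) a$label, "")
  edge <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m <- oracle_match(annotations[[i]], annotations[[j]], offset)
      edge[[paste(i, j)]] <- m$pair_map
    }
  }
  assigned <- lapply(annotations, function(a)
    setNames(rep(FALSE, nrow(a$genes)), a$genes$uid))
  clusters <- list()
  for (i in seq_len(n)) {
    for (uid in annotations[[i]]$genes$uid) {
      if (assigned[[i]][[uid]]) next
      mem_i <- i; mem_u <- uid
      if (i < n) for (j in seq(i + 1, n)) {
        cands <- vapply(seq_along(mem_i), function(k) {
          if (mem_i[k] < j) {
            mp <- edge[[paste(mem_i[k], j)]]
            if (mem_u[k] %in% names(mp)) unname(mp[[mem_u[k]]])
            else NA_character_
          } else NA_character_
        }, "")
        if (anyNA(cands) || length(unique(cands)) != 1L) next
        if (assigned[[j]][[cands[1]]]) next
        mem_i <- c(mem_i, j); mem_u <- c(mem_u, cands[1])
      }
      for (k in seq_along(mem_i)) assigned[[mem_i[k]]][[mem_u[k]]] <- TRUE
      clusters[[length(clusters) + 1L]] <-
        data.frame(label = labels[mem_i], uid = mem_u,
                   stringsAsFactors = FALSE)
    }
  }
  clusters
}

# canonical string form of a clustering for comparison
cluster_signature <- function(cluster_list) {
  sort(vapply(cluster_list, function(cl)
    paste(sort(paste(cl$label, cl$uid, sep = ":")), collapse = ","), ""))
}
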