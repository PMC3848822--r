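# Independent brute-force oracles. These deliberately use different
# algorithms (pairwise union-find, per-group loops, regex) from the
# implementation they check.

# Union-find on integer ids.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

# Brute-force window-rule clustering: union all hit pairs within the
# join distance, form +-w intervals per component, then (optionally)
# iterate pairwise interval merging to a fixpoint.
oracle_window_clusters <- function(hit_idx, n_genes, w,
                                   join_rule = "hit_in_window",
                                   merge = TRUE) {
  hit_idx <- sort(unique(hit_idx))
  k <- length(hit_idx)
  if (k == 0) {
    return(tibble::tibble(first_index = integer(), last_index = integer(),
                          hits = list()))
  }
  join_gap <- if (join_rule == "hit_in_window") w else 2 * w
  parent <- uf_new(k)
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (abs(hit_idx[i] - hit_idx[j]) <= join_gap) {
          parent <- uf_union(parent, i, j)
        }
      }
    }
  }
  comp <- vapply(seq_len(k), function(i) uf_find(parent, i), integer(1))
  intervals <- lapply(unique(comp), function(cc) {
    h <- hit_idx[comp == cc]
    list(first = max(0L, min(h) - w),
         last = min(n_genes - 1L, max(h) + w),
         hits = h)
  })
  if (merge) {
    repeat {
      merged <- FALSE
      for (i in seq_along(intervals)) {
        for (j in seq_along(intervals)) {
          if (i < j &&
              intervals[[i]]$first <= intervals[[j]]$last &&
              intervals[[j]]$first <= intervals[[i]]$last) {
            intervals[[i]] <- list(
              first = min(intervals[[i]]$first, intervals[[j]]$first),
              last = max(intervals[[i]]$last, intervals[[j]]$last),
              hits = sort(c(intervals[[i]]$hits, intervals[[j]]$hits))
            )
            intervals[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  ord <- order(vapply(intervals, function(x) x$first, integer(1)))
  tibble::tibble(
    first_index = vapply(intervals[ord], function(x) x$first, integer(1)),
    last_index = vapply(intervals[ord], function(x) x$last, integer(1)),
    hits = lapply(intervals[ord], function(x) x$hits)
  )
}

# Per-group min-copy shared count by direct iteration.
oracle_shared_count <- function(groups, a, b) {
  total <- 0L
  for (g in unique(groups$group_id)) {
    na <- sum(groups$group_id == g & groups$genome_id == a)
    nb <- sum(groups$group_id == g & groups$genome_id == b)
    total <- total + min(na, nb)
  }
  total
}

# Regex oracle for the PepM motif (first match position or 0).
oracle_pepm <- function(s) {
  m <- regexpr("EDK.{5}NS", s)
  if (m[1] == -1) 0L else as.integer(m[1])
}

# Union-find family partition over a thresholded similarity matrix with
# the class-intersection requirement.
oracle_family_partition <- function(simmat, class_sets, threshold) {
  n <- nrow(simmat)
  parent <- uf_new(n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (simmat[i, j] >= threshold &&
            length(intersect(class_sets[[i]], class_sets[[j]])) > 0) {
          parent <- uf_union(parent, i, j)
        }
      }
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# Rand index between two partitions (vectors of component labels).
rand_index <- function(p1, p2) {
  n <- length(p1)
  if (n < 2) return(1)
  agree <- 0
  total <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1
      same1 <- p1[i] == p1[j]
      same2 <- p2[i] == p2[j]
      if (same1 == same2) agree <- agree + 1
    }
  }
  agree / total
}
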