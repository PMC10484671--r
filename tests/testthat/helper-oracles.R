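# Independent oracles used to validate the package's distance and
# clustering routines. These deliberately avoid the code paths under test:
# the edit distance is a hand-written dynamic program, and the clustering
# oracle recomputes cluster-pair linkage from the raw matrix at every step.

dp_levenshtein <- function(a, b) {
  x <- strsplit(a, NULL)[[1L]]
  y <- strsplit(b, NULL)[[1L]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,
                         cur[j] + 1L,
                         prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Naive complete-linkage agglomeration over a labeled distance matrix.
# Tie-break: leaves start in natural-sort label order; among equal-height
# candidate merges the pair of earliest-created clusters wins. Returns the
# merge heights and a function cutting at a similarity threshold.
naive_complete_linkage <- function(D) {
  labels <- rownames(D)
  ord <- order_naturally(labels)
  D <- D[ord, ord, drop = FALSE]
  labels <- labels[ord]
  clusters <- lapply(seq_along(labels), identity)
  heights <- numeric(0)
  merges <- list()
  snapshot <- list(list(members = clusters))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(D[clusters[[i]], clusters[[j]], drop = FALSE])
        if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$h)
    snapshot[[length(snapshot) + 1L]] <- list(members = clusters, h = best$h)
  }
  cut_at <- function(similarity) {
    h <- (1 - similarity) + 1e-9
    state <- snapshot[[1L]]$members
    for (k in seq_along(heights)) {
      if (heights[k] <= h) state <- snapshot[[k + 1L]]$members else break
    }
    lapply(state, function(idx) sort(labels[idx]))
  }
  list(heights = heights, cut = cut_at, labels = labels)
}

# partition (named label vector) -> canonical list of sorted member sets
partition_sets <- function(labels_vec) {
  canonical_sets(split(names(labels_vec), labels_vec))
}

canonical_sets <- function(sets) {
  sets <- unname(lapply(sets, function(s) sort(unname(s))))
  sets[order(vapply(sets, `[[`, "", 1L))]
}

order_naturally <- function(x) {
  # minimal natural ordering for the oracle (digits compare numerically)
  key <- gsub("(\\d+)", "~\\1~", x)
  parts <- strsplit(key, "~")
  n_tok <- max(lengths(parts))
  keys <- list()
  for (i in seq_len(n_tok)) {
    tok <- vapply(parts, function(p) if (length(p) >= i) p[[i]] else "", "")
    num <- suppressWarnings(as.numeric(tok))
    keys[[2L * i - 1L]] <- ifelse(is.na(num), Inf, num)
    keys[[2L * i]] <- ifelse(is.na(num), tok, "")
  }
  do.call(order, keys)
}

random_sequences <- function(n, len_range = c(20L, 30L)) {
  vapply(seq_len(n), function(i) {
    L <- sample(seq(len_range[1L], len_range[2L]), 1L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
}
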