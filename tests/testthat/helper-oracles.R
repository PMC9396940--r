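# Brute-force oracles, independent of the package implementation paths.

# best gapless match of read vs named character refs, both strands;
# tie order: longest, fewest mismatches, lowest id, sense first
bf_best_match <- function(read, refs, min_len, max_mm) {
  cands <- list()
  for (orient in c("sense", "antisense")) {
    rd <- if (orient == "sense") read else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read)))
    rv <- strsplit(rd, "")[[1L]]
    for (id in sort(names(refs))) {
      fv <- strsplit(refs[[id]], "")[[1L]]
      for (d in (-(length(rv) - min_len)):(length(fv) - min_len)) {
        i0 <- max(1L, 1L - d); i1 <- min(length(rv), length(fv) - d)
        if (i1 - i0 + 1L < min_len) next
        mmv <- rv[i0:i1] != fv[(i0:i1) + d]
        left <- 1L; cnt <- 0L; mmpos <- integer(0)
        bl <- 0L; bm <- 0L
        for (r in seq_along(mmv)) {
          if (mmv[r]) { mmpos <- c(mmpos, r); cnt <- cnt + 1L }
          while (cnt > max_mm) {
            left <- mmpos[1L] + 1L; mmpos <- mmpos[-1L]; cnt <- cnt - 1L
          }
          len <- r - left + 1L
          if (len >= min_len &&
              (len > bl || (len == bl && cnt < bm))) {
            bl <- len; bm <- cnt
          }
        }
        if (bl >= min_len)
          cands[[length(cands) + 1L]] <-
            data.frame(id = id, len = bl, mm = bm, orient = orient,
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cands)) return(NULL)
  tab <- do.call(rbind, cands)
  tab <- tab[order(-tab$len, tab$mm, tab$id, tab$orient != "sense"), ]
  tab[1L, ]
}

# per-base repeat subtraction for one mate interval (0-based half-open)
bf_unique <- function(mate, repeats, min_unique) {
  pos <- mate$start:(mate$end - 1L)
  free <- !vapply(pos, function(p) any(
    repeats$chrom == mate$chrom & repeats$start <= p & repeats$end > p),
    logical(1))
  if (!any(free)) return(NULL)
  r <- rle(free)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  b <- runs[which.max(r$lengths[runs])]
  if (r$lengths[b] < min_unique) return(NULL)
  data.frame(start = pos[starts[b]], end = pos[ends[b]] + 1L)
}

# union-find partition of candidate unique intervals within merge_gap,
# per (element, strand) group
bf_cluster_partition <- function(cands, merge_gap) {
  key <- paste(cands$element_id, cands$transcript_strand)
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    parent <- seq_along(idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      ga <- cands[idx[a], ]; gb <- cands[idx[b], ]
      gap <- max(gb$unique_start - ga$unique_end,
                 ga$unique_start - gb$unique_end, 0L)
      if (gap <= merge_gap) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    for (r in unique(roots))
      out[[length(out) + 1L]] <- sort(idx[roots == r])
  }
  out[order(vapply(out, `[`, integer(1), 1L))]
}

bf_hedges <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  (1 - 3 / (4 * (n1 + n2) - 9)) * (mean(x) - mean(y)) / sp
}

bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
bf_mw_exact_p <- function(x, y) {
  n1 <- length(x); vals <- c(x, y)
  u_obs <- sum(vapply(x, function(a) sum(a > y) + 0.5 * sum(a == y),
                      numeric(1)))
  picks <- combn(length(vals), n1)
  us <- apply(picks, 2L, function(ix) {
    a <- vals[ix]; b <- vals[-ix]
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b),
               numeric(1)))
  })
  mu <- n1 * (length(vals) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# naive per-base scale-regions profile (track as 0-based data.frame)
bf_metaprofile <- function(track, elements, before, body, after, bin) {
  val_at <- function(chrom, p) {
    r <- track$value[track$chrom == chrom & track$start <= p &
                       track$end > p]
    if (length(r)) r[1L] else 0
  }
  t(vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    pos <- (e$start - before):(e$end + after - 1L)
    v <- vapply(pos, function(p) val_at(e$chrom, p), numeric(1))
    if (e$strand == "-") v <- rev(v)
    w <- e$end - e$start
    vb <- v[(before + 1L):(before + w)]
    vb <- vb[floor((0:(body - 1L)) * w / body) + 1L]
    row <- c(v[seq_len(before)], vb, v[(before + w + 1L):length(v)])
    vapply(seq_len(length(row) / bin), function(b)
      mean(row[((b - 1L) * bin + 1L):(b * bin)]), numeric(1))
  }, numeric((before + body + after) / bin)))
}

random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
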