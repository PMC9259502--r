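#' Specify the pair of bead jars
#'
#' The beads tasks use two jars with complementary color ratios. Jar A is the
#' jar whose dominant bead color is coded `1`; jar B dominates in color `0`.
#' A single number, the dominant fraction `q`, determines both emission
#' distributions: P(color 1 | jar A) = q and P(color 1 | jar B) = 1 - q.
#'
#' @param dominant_fraction Proportion of the dominant color in each jar,
#'   strictly between 0.5 and 1. Default 0.8 (the classic 80:20 jars).
#' @return An object of class `jar_spec`.
#' @examples
#' jar_spec()           # 80:20 jars
#' jar_spec(0.6)        # harder discrimination
#' @export
jar_spec <- function(dominant_fraction = 0.8) {
  if (!is.numeric(dominant_fraction) || length(dominant_fraction) != 1L ||
      !is.finite(dominant_fraction)) {
    stop("dominant_fraction must be a single finite number")
  }
  if (dominant_fraction <= 0.5 || dominant_fraction >= 1) {
    stop("dominant_fraction must be strictly between 0.5 and 1")
  }
  structure(list(dominant_fraction = dominant_fraction, n_colors = 2L),
            class = "jar_spec")
}

#' @export
print.jar_spec <- function(x, ...) {
  q <- x$dominant_fraction
  cat(sprintf("Two-jar spec: %.0f:%.0f ratio (q = %g)\n", 100 * q, 100 * (1 - q), q))
  invisible(x)
}

# P(bead color | jar): jar 1 (A) dominant in color 1, jar 2 (B) in color 0.
emission_prob <- function(bead_color, jar_id, jar) {
  q <- jar$dominant_fraction
  ifelse(jar_id == 1L,
         ifelse(bead_color == 1L, q, 1 - q),
         ifelse(bead_color == 1L, 1 - q, q))
}

#' Construct a bead sequence
#'
#' An ordered record of bead colors together with the hidden jar that produced
#' each bead. For the probability-estimation task the jar switches exactly once;
#' `reversal_index` is the (1-based) bead index after which the switch occurs.
#'
#' @param beads Integer vector of color codes in {0, 1}.
#' @param true_jar_path Integer vector of jar identities (1 = jar A, 2 = jar B),
#'   one per bead.
#' @param reversal_index Optional bead index after which the jar switches;
#'   `NA` for fixed-jar (draws-to-decision) sequences.
#' @return An object of class `bead_sequence`.
#' @export
bead_sequence <- function(beads, true_jar_path, reversal_index = NA_integer_) {
  beads <- as.integer(beads)
  true_jar_path <- as.integer(true_jar_path)
  if (length(beads) != length(true_jar_path)) {
    stop("beads and true_jar_path must have equal length")
  }
  if (!all(beads %in% c(0L, 1L))) stop("bead colors must be coded 0 or 1")
  if (!all(true_jar_path %in% c(1L, 2L))) stop("jar identities must be 1 or 2")
  if (!is.na(reversal_index)) {
    reversal_index <- as.integer(reversal_index)
    n <- length(beads)
    if (reversal_index < 1L || reversal_index >= n) {
      stop("reversal_index must satisfy 1 <= reversal_index < length(beads)")
    }
    pre <- true_jar_path[seq_len(reversal_index)]
    post <- true_jar_path[(reversal_index + 1L):n]
    if (length(unique(pre)) != 1L || length(unique(post)) != 1L ||
        pre[1L] == post[1L]) {
      stop("true_jar_path must be constant before and after the reversal and differ across it")
    }
  }
  structure(list(beads = beads, true_jar_path = true_jar_path,
                 reversal_index = reversal_index),
            class = "bead_sequence")
}

#' @export
length.bead_sequence <- function(x) length(x$beads)

#' @export
print.bead_sequence <- function(x, ...) {
  cat(sprintf("Bead sequence (%d beads%s): %s\n", length(x$beads),
              if (is.na(x$reversal_index)) ""
              else sprintf(", reversal after bead %d", x$reversal_index),
              paste(x$beads, collapse = "")))
  invisible(x)
}

#' Generate a pool of fixed-jar sequences for the draws-to-decision task
#'
#' Each sequence is produced by fixing a source jar (alternating across the
#' pool so both jars are equally represented) and drawing bead colors i.i.d.
#' from that jar's emission distribution. The default pool of 16 sequences of
#' 10 beads each matches the task design in which each participant's five
#' blocks are sampled from a pool of 16 possible sequences of up to 10 draws.
#'
#' @param jar A [jar_spec()].
#' @param pool_size Number of sequences (default 16).
#' @param length Beads per sequence (default 10).
#' @param seed Integer seed; the pool is reproducible under it.
#' @param max_retries Bounded number of redraws used to keep sequences distinct.
#' @return An object of class `sequence_pool`: a list of [bead_sequence()]s
#'   with a provenance attribute recording the generating settings.
#' @examples
#' pool <- make_sequence_pool(jar_spec(), seed = 1)
#' length(pool$sequences)
#' @export
make_sequence_pool <- function(jar, pool_size = 16L, length = 10L, seed = 1L,
                               max_retries = 1000L) {
  stopifnot(inherits(jar, "jar_spec"))
  pool_size <- as.integer(pool_size)
  length <- as.integer(length)
  if (pool_size < 1L || length < 1L) stop("pool_size and length must be >= 1")
  q <- jar$dominant_fraction
  seqs <- with_seed(seed, {
    out <- vector("list", pool_size)
    seen <- character(0)
    retries <- 0L
    i <- 1L
    while (i <= pool_size) {
      src <- if (i %% 2L == 1L) 1L else 2L  # balance source jars across the pool
      p1 <- if (src == 1L) q else 1 - q
      beads <- as.integer(stats::runif(length) < p1)
      key <- paste0(src, ":", paste(beads, collapse = ""))
      if (key %in% seen) {
        retries <- retries + 1L
        if (retries > max_retries) {
          stop("degenerate configuration: could not generate distinct sequences")
        }
        next
      }
      seen <- c(seen, key)
      out[[i]] <- bead_sequence(beads, rep(src, length))
      i <- i + 1L
    }
    out
  })
  structure(list(sequences = seqs,
                 provenance = list(q = q, pool_size = pool_size,
                                   length = length, seed = seed)),
            class = "sequence_pool")
}

#' Generate a 30-bead probability-estimation sequence with one jar reversal
#'
#' Beads 1..`reversal_after` are drawn from one jar and the remainder from the
#' other; the task's standard design draws 30 beads with the switch after
#' bead 15.
#'
#' @param jar A [jar_spec()].
#' @param length Sequence length (default 30).
#' @param reversal_after Bead index after which the jar switches (default 15).
#' @param seed Integer seed.
#' @param first_jar Source jar for the pre-reversal segment (1 or 2).
#' @return A [bead_sequence()] with `reversal_index` set.
#' @export
make_probest_sequence <- function(jar, length = 30L, reversal_after = 15L,
                                  seed = 1L, first_jar = 1L) {
  stopifnot(inherits(jar, "jar_spec"))
  length <- as.integer(length)
  reversal_after <- as.integer(reversal_after)
  if (reversal_after < 1L || reversal_after >= length) {
    stop("reversal_after must satisfy 1 <= reversal_after < length")
  }
  first_jar <- as.integer(first_jar)
  stopifnot(first_jar %in% c(1L, 2L))
  second_jar <- if (first_jar == 1L) 2L else 1L
  path <- c(rep(first_jar, reversal_after), rep(second_jar, length - reversal_after))
  q <- jar$dominant_fraction
  p1 <- ifelse(path == 1L, q, 1 - q)
  beads <- with_seed(seed, as.integer(stats::runif(length) < p1))
  bead_sequence(beads, path, reversal_after)
}

#' Write / read a sequence pool as CSV
#'
#' One row per bead: `sequence_id`, `bead_index`, `color`, `source_jar`.
#'
#' @param pool A `sequence_pool`.
#' @param path File path.
#' @return `write_sequence_pool` returns `path` invisibly;
#'   `read_sequence_pool` returns a `sequence_pool`.
#' @export
write_sequence_pool <- function(pool, path) {
  stopifnot(inherits(pool, "sequence_pool"))
  rows <- do.call(rbind, lapply(seq_along(pool$sequences), function(i) {
    s <- pool$sequences[[i]]
    data.frame(sequence_id = i, bead_index = seq_along(s$beads),
               color = s$beads, source_jar = s$true_jar_path)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_pool
#' @export
read_sequence_pool <- function(path) {
  df <- utils::read.csv(path)
  need <- c("sequence_id", "bead_index", "color", "source_jar")
  if (!all(need %in% names(df))) {
    stop("pool CSV must have columns: ", paste(need, collapse = ", "))
  }
  ids <- sort(unique(df$sequence_id))
  seqs <- lapply(ids, function(i) {
    d <- df[df$sequence_id == i, ]
    d <- d[order(d$bead_index), ]
    bead_sequence(d$color, d$source_jar)
  })
  structure(list(sequences = seqs, provenance = list(source = path)),
            class = "sequence_pool")
}
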