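## Motif templates: the local wiring patterns replicated during network
## growth. A template is a small role-labelled directed pattern; exactly
## one slot carries the "x" (master regulator) role, which is the node
## recycled into the hierarchy set H after instantiation.

new_motif_template <- function(name, kinds, x_slot, from, to, sign) {
  n <- length(kinds)
  stopifnot(x_slot >= 1L, x_slot <= n, length(from) == length(to),
            length(sign) == length(from))
  # miRNA-sourced edges are always repressive
  sign[kinds[from] == "mirna"] <- "repression"
  structure(
    list(name = name,
         slots = data.frame(slot = seq_len(n), kind = kinds,
                            is_x = seq_len(n) == x_slot),
         edges = data.frame(from = as.integer(from), to = as.integer(to),
                            sign = sign)),
    class = "motif_template")
}

#' @export
print.motif_template <- function(x, ...) {
  cat("motif_template:", x$name, "-", nrow(x$slots), "slots,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

rand_sign <- function(n = 1L) sample(c("activation", "repression"), n, replace = TRUE)

#' Default motif registry
#'
#' Returns the catalogue of motif template generators used during network
#' growth: autoregulation, feed-forward loop, feedback loop, single-input
#' module (fan-out 2-5), dense overlapping regulons (2-4 regulators x 2-4
#' targets), and the miRNA-containing feed-forward and feedback variants.
#' Each entry is a zero-argument function drawing a concrete
#' \code{motif_template} from the current RNG stream; structural sizes
#' and edge signs vary between draws. Entries with \code{needs_mirna}
#' are excluded when the configuration has no miRNAs.
#'
#' The registry is a plain named list, so users can extend it with their
#' own template generators and pass it to \code{\link{build_network}}.
#'
#' @return named list of generator entries, each a list with fields
#'   \code{make} (function) and \code{needs_mirna} (logical).
#' @export
default_motif_registry <- function() {
  list(
    autoregulation = list(needs_mirna = FALSE, make = function() {
      new_motif_template("autoregulation", "gene", 1L, 1L, 1L, rand_sign())
    }),
    feed_forward_loop = list(needs_mirna = FALSE, make = function() {
      new_motif_template("feed_forward_loop", rep("gene", 3L), 1L,
                         c(1L, 1L, 2L), c(2L, 3L, 3L), rand_sign(3L))
    }),
    feedback_loop = list(needs_mirna = FALSE, make = function() {
      s <- sample(2:3, 1L)
      new_motif_template("feedback_loop", rep("gene", s), 1L,
                         seq_len(s), c(seq_len(s)[-1L], 1L), rand_sign(s))
    }),
    single_input_module = list(needs_mirna = FALSE, make = function() {
      k <- sample(2:5, 1L)
      new_motif_template("single_input_module", rep("gene", k + 1L), 1L,
                         rep(1L, k), 1L + seq_len(k), rep(rand_sign(), k))
    }),
    dense_overlapping_regulons = list(needs_mirna = FALSE, make = function() {
      r <- sample(2:4, 1L); tg <- sample(2:4, 1L)
      pairs <- expand.grid(from = seq_len(r), to = r + seq_len(tg))
      keep <- runif(nrow(pairs)) < 0.6
      # guarantee every regulator and every target participates
      pick1 <- function(idx) idx[sample.int(length(idx), 1L)]
      for (i in seq_len(r)) if (!any(keep & pairs$from == i))
        keep[pick1(which(pairs$from == i))] <- TRUE
      for (j in r + seq_len(tg)) if (!any(keep & pairs$to == j))
        keep[pick1(which(pairs$to == j))] <- TRUE
      pairs <- pairs[keep, , drop = FALSE]
      new_motif_template("dense_overlapping_regulons", rep("gene", r + tg),
                         1L, pairs$from, pairs$to, rand_sign(nrow(pairs)))
    }),
    mirna_feed_forward_loop = list(needs_mirna = TRUE, make = function() {
      new_motif_template("mirna_feed_forward_loop",
                         c("gene", "mirna", "gene"), 1L,
                         c(1L, 1L, 2L), c(2L, 3L, 3L),
                         c("activation", rand_sign(), "repression"))
    }),
    mirna_feedback_loop = list(needs_mirna = TRUE, make = function() {
      new_motif_template("mirna_feedback_loop", c("gene", "mirna"), 1L,
                         c(1L, 2L), c(2L, 1L),
                         c("activation", "repression"))
    })
  )
}

## Sample one concrete template from a registry (uniform over admissible
## families, structural sizes drawn inside the generator). When only
## miRNAs remain to be wired, the family must contain a miRNA slot,
## otherwise an instantiation could consume no available node.
sample_motif_template <- function(registry, has_mirnas, require_mirna = FALSE) {
  ok <- vapply(registry, function(e) {
    if (require_mirna) e$needs_mirna else has_mirnas || !e$needs_mirna
  }, logical(1))
  entries <- registry[ok]
  if (!length(entries)) stop("no admissible motif templates in registry")
  entries[[sample.int(length(entries), 1L)]]$make()
}

## Per-slot degree increments implied by a template's internal edges.
## Genes are scored on total degree (self-loop counts twice); miRNAs on
## the in/out split.
slot_degree_deltas <- function(template) {
  n <- nrow(template$slots)
  din <- tabulate(template$edges$to, n)
  dout <- tabulate(template$edges$from, n)
  data.frame(slot = seq_len(n), kind = template$slots$kind,
             is_x = template$slots$is_x,
             d_in = din, d_out = dout, d_tot = din + dout)
}
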