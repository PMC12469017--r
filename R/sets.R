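# Internal node-set utilities. Node sets are character vectors; every model
# carries `nodes`, a fixed ordered ground set used for canonicalization,
# tie-breaking and deterministic iteration.

sf_check_labels <- function(nodes, x, what = "set") {
  x <- as.character(x)
  bad <- setdiff(x, nodes)
  if (length(bad) > 0L) {
    stop(sprintf("unknown node label(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x)) {
    stop(sprintf("duplicate node label(s) in %s", what), call. = FALSE)
  }
  x
}

# canonical form: sorted by position in the ground order
sf_canon <- function(nodes, x, what = "set") {
  x <- sf_check_labels(nodes, x, what)
  x[order(match(x, nodes))]
}

sf_key <- function(x) paste(x, collapse = ",")

sf_complement <- function(nodes, B) nodes[!(nodes %in% B)]

# all subsets of `nodes` as a list of canonical character vectors,
# enumerated in lexicographic order of the ground-index sequence
# (prefixes first, so {} < {1} < {1,2} < {2})
sf_subsets <- function(nodes, include_empty = TRUE) {
  n <- length(nodes)
  if (n > 20L) stop("subset enumeration limited to 20 nodes", call. = FALSE)
  masks <- seq.int(0L, 2^n - 1L)
  subs <- lapply(masks, function(m) nodes[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L])
  if (!include_empty) subs <- subs[-1L]
  keys <- vapply(subs, function(s) paste(sprintf("%04d", match(s, nodes)), collapse = ""), "")
  subs[order(keys, method = "radix")]
}

# lexicographic comparison of two canonical sets under the ground order;
# shorter prefix wins on ties (so {1} < {1,2} < {1,3} < {2})
sf_lex_less <- function(nodes, a, b) {
  ia <- match(a, nodes); ib <- match(b, nodes)
  k <- min(length(ia), length(ib))
  if (k > 0L) {
    for (i in seq_len(k)) {
      if (ia[i] != ib[i]) return(ia[i] < ib[i])
    }
  }
  length(ia) < length(ib)
}

sf_is_subset <- function(a, b) all(a %in% b)

sf_stop_guard <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}
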