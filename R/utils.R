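# recursive helpers over parameter trees (nested lists of numeric arrays)

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}

tree_map3 <- function(f, x, y, z) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map3(f, x[[i]], y[[i]], z[[i]])
    out
  } else f(x, y, z)
}

# derive a per-stage 32-bit seed from a global seed and a stage tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * (31 ^ (seq_along(utf8ToInt(as.character(tag))) %% 7)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
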