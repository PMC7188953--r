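#' Serialize a trained network to JSON
#'
#' Stores layer sizes, weights, biases, seed and the training record, and
#' reads them back into an `mlp_net`.
#'
#' @param net an `mlp_net`.
#' @param path JSON file path.
#' @return `path` invisibly (`write_mlp`); an `mlp_net` (`read_mlp`).
#' @export
write_mlp <- function(net, path) {
  jsonlite::write_json(
    list(layer_sizes = net$layer_sizes,
         W = lapply(net$W, function(m) list(dim = dim(m), values = c(m))),
         b = net$b, seed = net$seed, record = net$record),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(j$W$dim, function(d) NULL)
  W <- vector("list", length(j$b))
  for (l in seq_along(W))
    W[[l]] <- matrix(j$W$values[[l]], j$W$dim[[l]][1], j$W$dim[[l]][2])
  structure(list(W = W, b = lapply(j$b, as.numeric),
                 layer_sizes = as.integer(j$layer_sizes),
                 seed = as.integer(j$seed),
                 record = j$record),
            class = "mlp_net")
}
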