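# Scene cache with capacity limit, access accounting and eviction.
#
# Scenes (one raster tile at one timestamp for one variable) are the unit
# of fetching and caching. A pluggable provider materializes missing
# scenes; cache hits only update the access accounting. Two eviction
# strategies are offered: least-frequently-used (default — scenes are
# ranked by how often they have been accessed since fetch and the least
# accessed are deleted first) and least-recently-used. Eviction
# tie-breaks are deterministic: oldest last access, then lexicographic
# key. Recency uses a logical clock, so replays are reproducible.

#' Create a scene cache
#'
#' @param capacity maximum number of scenes held (> 0; `Inf` for
#'   unbounded)
#' @param strategy `"lfu"` (least frequently used, default) or `"lru"`
#'   (least recently used)
#' @param retries number of extra provider attempts after a failure
#' @return a `scene_cache` object (environment)
#' @export
scene_cache <- function(capacity = Inf, strategy = c("lfu", "lru"),
                        retries = 2) {
  strategy <- match.arg(strategy)
  if (!is.numeric(capacity) || length(capacity) != 1 || is.na(capacity) ||
      capacity <= 0)
    et_validation_error("cache capacity must be positive")
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())   # key -> payload
  e$meta <- list()                          # key -> list(count, last)
  e$clock <- 0L
  e$capacity <- capacity
  e$strategy <- strategy
  e$retries <- retries
  e$stats <- list(hits = 0L, misses = 0L, evictions = 0L)
  class(e) <- "scene_cache"
  e
}

#' @export
print.scene_cache <- function(x, ...) {
  cat(sprintf("<scene_cache> %s, %d/%s scenes, %d hits / %d misses / %d evictions\n",
              toupper(x$strategy), length(x$meta),
              format(x$capacity), x$stats$hits, x$stats$misses,
              x$stats$evictions))
  invisible(x)
}

#' Number of scenes currently cached / their keys
#'
#' @param cache a [scene_cache()]
#' @return scene count, or character vector of cached scene keys
#' @export
cache_size <- function(cache) length(cache$meta)

#' @rdname cache_size
#' @export
cache_keys <- function(cache) names(cache$meta)

#' Fetch a scene through the cache
#'
#' A cache hit increments the scene's access count and refreshes its
#' recency without invoking the provider; a miss invokes the provider
#' (retrying on failure per the cache's `retries` setting), stores the
#' payload, evicts down to capacity, and returns it.
#'
#' @param cache a [scene_cache()]
#' @param key scene key string
#' @param provider `function(key)` returning the scene payload
#' @return the scene payload
#' @export
get_scene <- function(cache, key, provider) {
  cache$clock <- cache$clock + 1L
  if (!is.null(cache$meta[[key]])) {
    m <- cache$meta[[key]]
    cache$meta[[key]] <- list(count = m$count + 1L, last = cache$clock)
    cache$stats$hits <- cache$stats$hits + 1L
    return(get(key, envir = cache$store))
  }
  payload <- NULL
  err <- NULL
  for (attempt in seq_len(cache$retries + 1)) {
    payload <- tryCatch(provider(key), error = function(e) {
      err <<- e
      NULL
    })
    if (!is.null(payload)) break
  }
  if (is.null(payload))
    et_fetch_error(sprintf("provider failed for scene '%s': %s", key,
                           conditionMessage(err)), scene_key = key)
  assign(key, payload, envir = cache$store)
  cache$meta[[key]] <- list(count = 1L, last = cache$clock)
  cache$stats$misses <- cache$stats$misses + 1L
  evict_to_capacity(cache)
  payload
}

# Policy-minimal eviction order over the given metadata: LFU ranks by
# access count then oldest recency then key; LRU by oldest recency then
# key. Shared by the live cache and the brute-force simulator in tests.
eviction_order <- function(meta, strategy) {
  keys <- names(meta)
  count <- vapply(meta, `[[`, 0L, "count")
  last <- vapply(meta, `[[`, 0L, "last")
  if (strategy == "lfu") keys[order(count, last, keys)]
  else keys[order(last, keys)]
}

#' Evict scenes down to the cache capacity
#'
#' Removes the policy-minimal scenes until the cache size is within
#' capacity. Ties are broken by oldest last access, then lexicographic
#' key. Returns the removed keys (empty when already under capacity).
#'
#' @param cache a [scene_cache()]
#' @return character vector of evicted keys
#' @export
evict_to_capacity <- function(cache) {
  removed <- character()
  n_drop <- cache_size(cache) - cache$capacity
  if (n_drop > 0) {
    victims <- head(eviction_order(cache$meta, cache$strategy), n_drop)
    for (k in victims) {
      rm(list = k, envir = cache$store)
      cache$meta[[k]] <- NULL
    }
    cache$stats$evictions <- cache$stats$evictions + length(victims)
    removed <- victims
  }
  removed
}

#' Scene provider backed by in-memory grid variables
#'
#' Materializes scene payloads by slicing the requested tile block out of
#' a list of `grid_variable`s — the provider used for synthetic fixtures
#' and manifest-loaded datasets.
#'
#' @param vars named list of `grid_variable`s (names = variable ids)
#' @return a `function(key)` suitable for [get_scene()]
#' @export
memory_provider <- function(vars) {
  force(vars)
  function(key) {
    p <- parse_scene_key(key)
    var <- vars[[p$variable]]
    if (is.null(var))
      stop(sprintf("unknown variable '%s'", p$variable))
    scene_payload(var, p$time_index, p$tile_x, p$tile_y)
  }
}

parse_scene_key <- function(key) {
  m <- regmatches(key, regexec("^(.*)\\|t([0-9]+)\\|x([0-9]+)\\.y([0-9]+)$", key))[[1]]
  if (!length(m)) et_validation_error(sprintf("malformed scene key '%s'", key))
  list(variable = m[2], time_index = as.integer(m[3]),
       tile_x = as.integer(m[4]), tile_y = as.integer(m[5]))
}

# Cache-aware scene accessor in the fetch() signature used by the
# interpolation layer.
cached_fetch <- function(cache, provider) {
  force(cache); force(provider)
  function(var, k, tx, ty)
    get_scene(cache, scene_key(var$id, k, tx, ty), provider)
}
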