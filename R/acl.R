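# Access control lists. Every object is created private: readable and
# writable only by its owner. The owner can share it with individual
# users at read or read-write level, or make it public (readable by
# everyone). The owner's read-write access can never be removed.

new_acl <- function(owner, safety_level = "private", shared_with = NULL) {
  structure(
    list(
      owner = owner,
      safety_level = safety_level,
      shared_with = shared_with %||% structure(character(), names = character())
    ),
    class = "acl"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.access_levels <- c("read", "read-write")
.safety_levels <- c("private", "public")

validate_acl <- function(acl, owner, store = NULL) {
  safety <- acl$safety_level %||% "private"
  if (!is.character(safety) || length(safety) != 1L || !safety %in% .safety_levels) {
    stop_bad_request(sprintf("invalid safety level '%s'", paste(safety, collapse = ",")))
  }
  shared <- acl$shared_with %||% structure(character(), names = character())
  if (length(shared) > 0) {
    shared <- unlist(shared)  # accept list or named vector
    if (is.null(names(shared)) || any(!nzchar(names(shared)))) {
      stop_bad_request("shared_with must map user ids to access levels")
    }
    if (any(!shared %in% .access_levels)) {
      bad <- shared[!shared %in% .access_levels][1]
      stop_bad_request(sprintf("invalid access level '%s'", bad))
    }
    if (owner %in% names(shared)) {
      stop_bad_request("the owner always has read-write access and cannot appear in shared_with")
    }
    if (!is.null(store)) {
      for (u in names(shared)) {
        if (!store$knows_user(u)) stop_bad_request(sprintf("unknown user '%s'", u))
      }
    }
  }
  new_acl(owner, safety, shared)
}

#' Effective access level of a user on an object
#'
#' The owner always has read-write access. A user listed in the ACL's
#' individual shares gets the listed level. Any user gets read access to
#' a public object. Otherwise access is none.
#'
#' @param acl an ACL as returned by [get_acl()].
#' @param actor user id (may be `NULL` for an anonymous caller).
#' @return `"none"`, `"read"` or `"read-write"`.
#' @export
effective_access <- function(acl, actor) {
  if (is.null(actor)) {
    return(if (identical(acl$safety_level, "public")) "read" else "none")
  }
  if (identical(actor, acl$owner)) return("read-write")
  if (actor %in% names(acl$shared_with)) return(unname(acl$shared_with[[actor]]))
  if (identical(acl$safety_level, "public")) return("read")
  "none"
}

#' Read an object's ACL
#'
#' @param store an [object_store()].
#' @param id object id.
#' @return the current ACL: `owner`, `safety_level`, `shared_with`.
#' @export
get_acl <- function(store, id) store$get_acl(id)

#' Replace an object's ACL
#'
#' Only the object owner may change permissions. The new ACL carries a
#' safety level (`"private"` or `"public"`) and a map of user ids to
#' individual access levels (`"read"` or `"read-write"`). ACL changes
#' are administrative state: they do not create a new object version.
#'
#' @param store an [object_store()].
#' @param id object id.
#' @param acl list with `safety_level` and `shared_with` (named character
#'   vector or list mapping user id to level).
#' @param actor acting user id; must be the owner.
#' @param recursive apply the same ACL to all contained objects (children
#'   through parent links, transitively) owned by `actor`.
#' @return the new ACL.
#' @export
set_acl <- function(store, id, acl, actor, recursive = FALSE) {
  store$set_acl(id, acl, actor, recursive)
}
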