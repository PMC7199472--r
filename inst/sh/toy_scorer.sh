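#!/bin/sh
# Toy docking stand-in: passes each SDF-dialect molecule record through
# unchanged and stamps a "> <docked>" data tag before the "$$$$"
# terminator, the way a docking tool emits a pose per input molecule. The
# "> <score>" tag already on the record plays the role of the binding
# affinity; no chemistry is computed.
#
# usage: toy_scorer.sh IN.sdf OUT.sdf
set -e
awk '
  /^\$\$\$\$$/ {
    print "> <docked>"
    print "yes"
    print ""
    print "$$$$"
    next
  }
  { print }
' "$1" > "$2"
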