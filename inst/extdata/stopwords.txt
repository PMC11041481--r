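a
an
the
is
are
was
were
be
been
being
am
of
for
to
with
on
in
at
by
from
as
or
and
per
this
that
it
patient
pt
he
she
his
her
they
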