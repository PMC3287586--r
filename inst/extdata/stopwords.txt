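a
an
the
and
or
but
if
then
than
that
this
these
those
of
in
on
at
by
for
with
without
to
from
into
onto
as
is
are
was
were
be
been
being
am
it
its
we
our
they
their
he
she
his
her
you
your
i
not
no
nor
so
such
which
who
whom
whose
what
when
where
why
how
all
any
both
each
few
more
most
other
some
only
own
same
can
could
will
would
shall
should
may
might
must
do
does
did
done
have
has
had
having
here
there
also
very
via
per
between
among
during
after
before
above
below
under
over
again
further
once
about
against
because
while
through
both
however
therefore
thus
although
moreover
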