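# Common general-English words in approximate descending frequency order.
# Used only to derive the rank-bucket feature of candidate terms
# (bucket = ceiling(rank / 100); words absent from the list fall in the
# out-of-list bucket). Curated by hand for the package; not a corpus count.
the
be
to
of
and
a
in
that
have
I
it
for
not
on
with
he
as
you
do
at
this
but
his
by
from
they
we
say
her
she
or
an
will
my
one
all
would
there
their
what
so
up
out
if
about
who
get
which
go
me
when
make
can
like
time
no
just
him
know
take
people
into
year
your
good
some
could
them
see
other
than
then
now
look
only
come
its
over
think
also
back
after
use
two
how
our
work
first
well
way
even
new
want
because
any
these
give
day
most
us
is
was
are
been
has
had
were
said
did
having
may
am
against
before
between
both
down
during
each
few
found
great
here
high
home
house
keep
last
left
life
little
long
made
man
many
might
more
much
must
name
never
next
night
number
off
old
once
open
own
part
place
point
put
right
same
saw
school
seem
should
show
small
sound
still
such
tell
thing
those
thought
three
through
today
together
too
took
turn
under
until
very
water
where
while
why
without
word
world
write
young
air
along
always
animal
another
answer
around
ask
away
big
book
boy
came
car
change
children
city
close
country
cut
different
does
dog
done
door
earth
eat
end
enough
every
example
eye
face
family
far
father
feet
find
fire
follow
food
form
four
girl
got
grow
hand
hard
head
hear
help
hold
hot
idea
important
kind
land
large
later
learn
leave
letter
light
line
list
live
love
low
mean
men
mile
miss
money
mother
move
near
need
often
page
paper
picture
play
quick
read
really
river
room
run
sea
second
sentence
set
side
soon
spell
start
state
stop
story
study
sun
sure
talk
tree
try
walk
watch
white
woman
yes
above
act
add
afraid
again
age
ago
agree
allow
almost
alone
already
although
among
amount
anger
apple
area
arm
art
baby
bad
ball
bank
base
beautiful
bed
begin
behind
believe
best
better
bird
black
blue
board
boat
body
bone
bottom
box
break
bring
brother
brought
build
burn
business
busy
buy
call
care
carry
case
catch
cause
center
certain
chance
child
choose
class
clean
clear
cold
color
common
company
complete
consider
contain
continue
control
cook
cool
corner
correct
cost
count
course
cover
create
cross
crowd
cry
dance
dark
dead
deal
decide
deep
desert
design
develop
die
direction
distance
divide
doctor
dollar
draw
dream
dress
drink
drive
drop
dry
ear
easy
edge
eight
either
else
energy
engine
enjoy
entire
especially
evening
event
ever
exactly
expect
experience
explain
fact
fall
fast
fear
feel
field
fight
figure
fill
final
fine
finger
finish
fish
fit
five
floor
fly
force
forest
forget
forward
free
fresh
friend
front
fruit
full
fun
future
game
garden
gas
general
gentle
glass
gold
gone
government
grass
green
ground
group
guess
half
happen
happy
heart
heavy
held
hill
history
hit
hope
horse
hour
huge
human
hundred
hunt
hurry
ice
include
increase
indeed
indicate
instead
interest
island
job
join
jump
key
kill
king
knew
lady
lake
language
laugh
law
lay
lead
less
level
lie
listen
lost
lot
loud
machine
main
major
map
mark
matter
maybe
measure
meet
member
memory
metal
method
middle
milk
million
mind
minute
moment
month
moon
morning
mountain
mouth
music
nation
natural
nature
nearly
necessary
neck
neighbor
nine
north
nose
note
nothing
notice
object
ocean
offer
office
oil
order
outside
past
pattern
pay
perhaps
person
phrase
pick
piece
plain
plan
plane
plant
pleasant
poor
position
possible
power
practice
prepare
present
president
press
pretty
probably
problem
process
produce
product
promise
prove
provide
pull
purpose
push
question
quiet
quite
race
radio
rain
raise
ran
reach
ready
real
reason
receive
record
red
remember
report
represent
require
rest
result
return
ride
ring
rise
road
rock
roll
rose
round
rule
safe
sail
salt
sand
sat
save
science
season
seat
seen
sell
send
sense
serve
seven
shape
share
sharp
ship
shoe
shop
short
shout
sign
silver
similar
simple
since
sing
single
sister
sit
six
size
skin
sky
sleep
slow
smile
snow
soft
soil
soldier
son
song
south
space
speak
special
speed
spend
spot
spread
spring
square
stand
star
stay
step
stick
stone
stood
store
straight
strange
stream
street
strong
subject
success
sudden
suggest
summer
supply
support
suppose
surface
surprise
sweet
system
table
tail
teach
team
ten
test
though
thousand
thus
tiny
tired
tone
tool
top
total
touch
toward
town
trade
train
travel
trip
trouble
true
truth
twenty
type
understand
unit
usual
valley
value
various
verb
view
village
visit
voice
wait
war
warm
wash
weather
week
weight
west
wheel
whether
whole
wide
wife
wild
win
wind
window
winter
wish
wonder
wood
wrote
yard
yellow
yet
able
accept
account
across
action
actually
address
admit
affect
afternoon
agency
ahead
alive
amazing
ancient
angry
announce
annual
anybody
anyone
anything
anyway
apart
appear
apply
argue
arrive
article
artist
assume
attack
attempt
attend
attention
audience
author
available
average
avoid
aware
bag
bar
basic
battle
beauty
become
beyond
bill
bit
blood
born
borrow
boss
bottle
bought
branch
brave
bread
bridge
brief
bright
broad
broke
brown
budget
building
bus
button
cake
camera
camp
capital
captain
card
career
careful
cat
cell
century
chair
challenge
character
charge
cheap
check
chest
chicken
chief
choice
church
circle
citizen
claim
club
coach
coast
coat
coffee
collect
college
combine
comfort
comment
community
compare
computer
concern
condition
conference
confirm
connect
contact
context
cop
copy
corn
couple
courage
court
cousin
crazy
credit
crime
culture
cup
current
customer
dad
daily
damage
danger
date
daughter
dear
death
debate
decade
decision
defense
degree
deliver
demand
describe
desk
despite
detail
determine
device
dinner
direct
discover
discuss
disease
dish
display
document
double
doubt
dozen
drug
due
dust
duty
eastern
economy
education
effect
effort
egg
election
electric
emotion
employee
empty
encourage
enemy
enter
equal
equipment
error
escape
establish
estimate
evidence
exam
excellent
except
exchange
excite
exercise
exist
expensive
expert
express
extra
factor
factory
fail
fair
faith
famous
fan
farm
fashion
fat
fault
favor
feature
feed
female
fence
festival
file
film
firm
fix
flag
flat
flight
flow
flower
focus
foot
foreign
forever
formal
former
fortune
frame
freedom
frequent
fuel
function
fund
funny
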